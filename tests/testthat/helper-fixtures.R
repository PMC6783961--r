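# Shared fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

bev <- function(role = "BS") fixture(paste0("bev_", role), function()
  synthetic_mab("bevacizumab_synthetic", role = role))
inf <- function(role = "BS") fixture(paste0("inf_", role), function()
  synthetic_mab("infliximab_synthetic", role = role))

# acquisition trimmed to the elution window of the three subunit clusters;
# all other parameters at package defaults
test_acq <- function(...) acquisition_params(rt_span = c(3.5, 13), ...)

noiseless_acq <- function(...) {
  acquisition_params(rt_span = c(3.5, 13), noise_sd0 = 0, noise_prop = 0,
                     baseline_level = 0, ...)
}

# independent elemental-composition oracle: its own residue formula table
# (entered from the standard amino-acid compositions) and atomic weights
oracle_peptide_avg_mass <- function(seq) {
  w <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
  comp <- list(
    A = c(3, 5, 1, 1, 0), R = c(6, 12, 4, 1, 0), N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0), C = c(3, 5, 1, 1, 1), Q = c(5, 8, 2, 2, 0),
    E = c(5, 7, 1, 3, 0), G = c(2, 3, 1, 1, 0), H = c(6, 7, 3, 1, 0),
    I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
    M = c(5, 9, 1, 1, 1), F = c(9, 9, 1, 1, 0), P = c(5, 7, 1, 1, 0),
    S = c(3, 5, 1, 2, 0), T = c(4, 7, 1, 2, 0), W = c(11, 10, 2, 1, 0),
    Y = c(9, 9, 1, 2, 0), V = c(5, 9, 1, 1, 0))
  atoms <- Reduce(`+`, comp[strsplit(seq, "")[[1]]]) + c(0, 2, 0, 1, 0)
  sum(atoms * w)
}

# forward model: noiseless centroid list of a charge-state envelope
envelope_centroids <- function(mass, z = NULL, sigma_z = 2.5, total = 1e5) {
  zc <- round(mass / 1200)
  if (is.null(z)) z <- (zc - 5):(zc + 5)
  w <- dnorm(z, zc, sigma_z)
  data.frame(mz = (mass + z * 1.00728) / z, intensity = total * w / sum(w))
}

# brute-force oracle for the number of oxidized sites: enumerate all site
# subsets and sum their probabilities
oracle_site_count_distribution <- function(p) {
  n <- length(p)
  d <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    d[sum(sel) + 1] <- d[sum(sel) + 1] + prod(ifelse(sel, p, 1 - p))
  }
  d
}

# full-design simulation + analysis, shared by the heavier acceptance checks
design_records <- function() fixture("design_records", function() {
  design <- table1_design()
  acq <- test_acq()
  levels_for <- function(mab_name) {
    if (grepl("bevacizumab", mab_name)) c("LC" = 3L, "Fd'" = 3L)
    else c("LC" = 1L, "Fd'" = 1L)
  }
  mabs <- list()
  for (m in unique(design$mab)) for (r in c("RP", "BS"))
    mabs[[paste(m, r)]] <- synthetic_mab(m, role = r)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    mab <- mabs[[paste(d$mab, d$role)]]
    run <- simulate_run(mab, default_scenario(mab), d$treatment, d$duration,
                        replicate = d$replicate, acq = acq,
                        seed = 5000L + 131L * i)
    lib <- mab_library(mab)
    ann <- assign_run(run, lib)
    out[[i]] <- ox_relative_abundance(run, ann, lib, levels_for(d$mab))
    rm(run); if (i %% 10 == 0) gc(verbose = FALSE)
  }
  do.call(rbind, out)
})

# the four 48 h forced-oxidation endpoint runs analysed end-to-end
endpoint_calls <- function() fixture("endpoint_calls", function() {
  acq <- test_acq()
  calls <- list()
  for (m in c("bevacizumab_synthetic", "infliximab_synthetic")) {
    mab <- synthetic_mab(m, role = "BS")
    run <- simulate_run(mab, default_scenario(mab), "oxi", 48,
                        acq = acq, seed = 480L)
    ann <- assign_run(run, mab_library(mab))
    calls[[m]] <- vapply(c("Fc/2", "LC", "Fd'"), function(su)
      most_abundant_species(ann, su)$n_ox, integer(1))
  }
  calls
})
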