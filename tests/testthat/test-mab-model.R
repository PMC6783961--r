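toy_mab <- function(role = "RP") {
  mab_definition("toy", heavy_chain = "QVQLMKSSCPAPELLGGPSVFMK",
                 light_chain = "DIQMK", product_role = role)
}

test_that("IdeS digestion cuts between the paired hinge glycines", {
  subs <- ides_digest(toy_mab())
  expect_named(subs, c("LC", "Fd'", "Fc/2"))
  expect_identical(subs[["LC"]]$sequence, "DIQMK")
  expect_identical(subs[["Fd'"]]$sequence, "QVQLMKSSCPAPELLG")
  expect_identical(subs[["Fc/2"]]$sequence, "GPSVFMK")
  expect_true(all(vapply(subs, `[[`, integer(1), "copies_per_mab") == 2L))
})

test_that("digestion conserves the heavy chain and always yields 3 kinds", {
  for (mab in list(toy_mab(), bev(), inf())) {
    subs <- ides_digest(mab)
    expect_length(unique(vapply(subs, `[[`, character(1), "kind")), 3L)
    expect_identical(paste0(subs[["Fd'"]]$sequence, subs[["Fc/2"]]$sequence),
                     mab$heavy_chain)
    # re-digestion is deterministic
    expect_identical(subs, ides_digest(mab))
  }
})

test_that("hinge-motif cardinality is enforced", {
  expect_error(mab_definition("x", "QVQLKSSCPAPGPSVFK", "DIQMK"), "exactly one")
  expect_error(mab_definition("x", "QLLGGASSLLGGK", "DIQMK"), "exactly one")
})

test_that("FASTA loading validates structure and alphabet", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">toy_HC heavy", "QVQLMKSSCPAPELLGGPSVFMK",
               ">toy_LC light", "DIQMK"), path)
  mab <- load_mab_fasta(path, role = "BS")
  expect_s3_class(mab, "mab_definition")
  expect_identical(mab$product_role, "BS")
  expect_identical(mab$light_chain, "DIQMK")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">toy_HC", "QVQLMKSSCPAPELLGGPSVFMK", ">toy_LC", "DIBQK"), bad)
  expect_error(load_mab_fasta(bad), "position 3")

  three <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a_HC", "QVQLMKSSCPAPELLGGPSVFMK", ">b_LC", "DIQMK",
               ">c_LC", "DIQMK"), three)
  expect_error(load_mab_fasta(three), "exactly 2")
})

test_that("methionine maps follow the sequence and the label offset", {
  su <- map_methionines(forceox:::.subunit_chain("Fc/2", "GPSVFMK"),
                        label_offset = 246)
  expect_identical(su$methionine_positions, 6L)
  expect_identical(su$site_labels, "M252")
  none <- map_methionines(forceox:::.subunit_chain("LC", "GPSVFK"))
  expect_length(none$site_labels, 0L)
})

test_that("the synthetic pair reproduces the published methionine layout", {
  sb <- ides_digest(bev())
  si <- ides_digest(inf())
  expect_identical(sb[["LC"]]$site_labels, "M4")
  expect_identical(sb[["Fd'"]]$site_labels, c("M34", "M83"))
  expect_setequal(sb[["Fc/2"]]$site_labels, c("M252", "M358", "M428"))
  expect_identical(si[["LC"]]$site_labels, "M55")
  expect_identical(si[["Fd'"]]$site_labels, c("M18", "M34", "M85"))
  expect_setequal(si[["Fc/2"]]$site_labels, c("M255", "M431"))
  # subunit masses are in the expected 22-27 kDa window
  for (s in c(sb, si))
    expect_true(average_mass(s$sequence) > 22000 &&
                  average_mass(s$sequence) < 27000)
})

test_that("methionine map comparison honours declared equivalences", {
  cmp <- compare_methionine_maps(bev(), inf(), synthetic_equivalences())
  expect_setequal(cmp[["Fd'"]]$shared, c("M34", "M83/85"))
  expect_identical(cmp[["Fd'"]]$unique_b, "M18")
  expect_length(cmp[["Fd'"]]$unique_a, 0L)
  expect_length(cmp[["LC"]]$shared, 0L)
  expect_identical(cmp[["LC"]]$unique_a, "M4")
  expect_identical(cmp[["LC"]]$unique_b, "M55")
  # identical products share everything
  self <- compare_methionine_maps(bev(), bev())
  for (k in names(self)) {
    expect_length(self[[k]]$unique_a, 0L)
    expect_length(self[[k]]$unique_b, 0L)
  }
})
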