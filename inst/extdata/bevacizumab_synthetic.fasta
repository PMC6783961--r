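>bevacizumab_synthetic_HC synthetic IgG1-like heavy chain
ELRCSAVAFSDQIQKERGETWSWLAKFTSQALQMDILLFNHEQILANPPGPEPTAWDANP
DSDEFIQRSDENREILGAFPGVMEPPVDALESGYDSHDLDTQKDPGGSSHVGQAEYAAVA
GTAIVTSLYYGTLLYSEEVPLALAGAEAADPLSDDRGLLLDHPAAPFDEDYGALRTELAE
CIVSPDIQLSPLTAFNKKSILLGEEKAQAGLVLVDNGGGKITVEDGQACPAPELLGGAAI
VFDQHPADEERMVQLDWTTQGNNIVFRASSDRKGFTNEVVESNNRIELAKSSETVFAAGY
FQADDNNLIANQRFGHNGDRCGAVTPTGAFDAVLGTEVEPRKAQTLFGSFGNPGDSVMAT
TCIATKKGQNPSVKVLHKFGEIKEIRDNLACHIVDYKLPPVQENKTVKSNVFGIARKTAV
TRQNYCGMNALVADEILLRLIASTNT
>bevacizumab_synthetic_LC synthetic IgG1-like light chain
DPTMGQVFSRKKVAESQTCIYGTDRHNSGSRAEATIWDTASEVAARIEYRLRAAAQAFFI
ASASEVYYVNAGQTVSYVDCRHKPTAERTAGASVPNHSADESESLDWIHFYGLIQSRGFS
LGQLLITNSEEPATTCRLRAEARLDTGLKLPKGARTANCYGSAAEAVPFLDPANVDFFAE
RDVKTFLWDQGQAGYGQRPSVAHSEFILEIEGAQ
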