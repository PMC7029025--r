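# Independent atomic constants used to freeze expected values; these are
# written out by hand so the oracle does not depend on the package tables.
ORA <- list(H = 1.0078250319, C = 12, N = 14.0030740052, O = 15.9949146221,
            S = 31.97207069, proton = 1.00727646)
ORA$water <- 2 * ORA$H + ORA$O
ORA$ch2 <- ORA$C + 2 * ORA$H

table1_peaks <- function() {
  read_peaklist(system.file("extdata", "table1_peaks.csv",
                            package = "lipoladder"))
}

# a random valid lipopeptide hypothesis (uses only the 19 supported letters)
random_spec <- function() {
  letters_ok <- c("G","A","S","P","V","T","L","I","N","D","Q","K","E","M",
                  "H","F","R","Y","W")
  lipopeptide_spec(
    paste(sample(letters_ok, sample(2:10, 1), replace = TRUE), collapse = ""),
    sample(3:20, 1),
    sample(c("cyclic", "linear"), 1))
}
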