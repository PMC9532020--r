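#' The 19-channel standard 10-20 montage
#'
#' Fixed channel order used throughout the pipeline:
#' Fp1, F7, T3, T5, F3, C3, P3, O1, Fp2, F8, T4, T6, F4, C4, P4, O2, Fz, Cz,
#' Pz. Temporal/posterior-temporal electrodes follow the older nomenclature
#' (T3/T4/T5/T6); the modern equivalents T7/T8/P7/P8 are accepted as aliases
#' when selecting channels from a recording.
#'
#' @return Character vector of 19 channel names in canonical order.
#' @export
standard_montage <- function() {
  c("Fp1", "F7", "T3", "T5", "F3", "C3", "P3", "O1",
    "Fp2", "F8", "T4", "T6", "F4", "C4", "P4", "O2",
    "Fz", "Cz", "Pz")
}

# old-name -> modern-name equivalences, usable in either direction
channel_aliases <- function() {
  c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")
}

# Match requested channel names against available ones, case-insensitively and
# through the alias table. Returns integer indices into `available`, with NA
# where no match exists.
match_channels <- function(requested, available) {
  al <- channel_aliases()
  lower <- tolower(available)
  vapply(requested, function(nm) {
    cand <- nm
    if (nm %in% names(al)) cand <- c(cand, al[[nm]])
    hit <- which(al == nm)
    if (length(hit)) cand <- c(cand, names(al)[hit])
    for (cn in cand) {
      i <- match(tolower(cn), lower)
      if (!is.na(i)) return(i)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}
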