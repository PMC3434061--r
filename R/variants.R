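#' Build the transcriptionally uncoupled architecture
#'
#' Convenience constructor for the variant in which hipB and hipA are
#' transcribed from two independent promoters into separate transcripts
#' (12 state variables), every rate constant keeping its wild-type value.
#' Equivalent to `build_network("uncoupled", promoter_copies)`.
#'
#' @param promoter_copies copies of each of the two promoters (default 1).
#' @return A `hipba_network`.
#' @export
build_uncoupled <- function(promoter_copies = 1L)
  build_network("uncoupled", promoter_copies)

#' Build the feedback-free architecture
#'
#' Convenience constructor for the variant without autorepression: only the
#' free promoter state exists and transcribes constitutively; the dimer and
#' complex still form and degrade but never bind the promoter. Equivalent
#' to `build_network("no_feedback", promoter_copies)`.
#'
#' @param promoter_copies promoter copy number (default 1).
#' @return A `hipba_network`.
#' @export
build_no_feedback <- function(promoter_copies = 1L)
  build_network("no_feedback", promoter_copies)
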