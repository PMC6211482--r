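#' @useDynLib BayesHLA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal symbol encoding shared by all modules and the C++ core:
#   1=A 2=C 3=G 4=T 5=N 6='-' ; 0 marks a column not covered by a read.
HLA_SYMBOLS <- c("A", "C", "G", "T", "N", "-")
SYM_A <- 1L; SYM_C <- 2L; SYM_G <- 3L; SYM_T <- 4L; SYM_N <- 5L; SYM_GAP <- 6L

#' Encode a sequence string into integer symbol codes
#'
#' @param x character scalar over the alphabet A, C, G, T, N, -
#' @return integer vector (1=A, 2=C, 3=G, 4=T, 5=N, 6=gap)
#' @keywords internal
encode_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  codes <- match(chars, HLA_SYMBOLS)
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("sequence contains symbols outside {A,C,G,T,N,-}: ",
         paste(bad, collapse = ", "))
  }
  codes
}

#' Decode integer symbol codes back into a sequence string
#' @param codes integer vector of symbol codes (0 rendered as '.')
#' @return character scalar
#' @keywords internal
decode_seq <- function(codes) {
  out <- character(length(codes))
  covered <- codes >= 1L & codes <= 6L
  out[covered] <- HLA_SYMBOLS[codes[covered]]
  out[!covered] <- "."
  paste(out, collapse = "")
}

is_base <- function(codes) codes >= 1L & codes <= 4L
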