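#' @useDynLib idpal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor dist dnorm integrate lm median optim
#'   pnorm predict qnorm quantile rnorm runif sd setNames splinefun uniroot
#'   var
#' @importFrom utils read.delim write.csv read.csv head tail
NULL

# canonical amino acids, alphabetical by one-letter code; this ordering fixes
# the composition block of every feature vector
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Boltzmann constant in kcal/(mol K)
KB_KCAL <- 0.0019872041

.AA_CODEPOINTS <- utf8ToInt(paste(AA_ALPHABET, collapse = ""))

# fast integer-code <-> string conversion used by the GA engine
codes_to_strings <- function(codes) {
  vapply(codes, function(cd) intToUtf8(.AA_CODEPOINTS[cd]), "")
}
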