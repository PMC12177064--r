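#' @importFrom stats coef lm quantile rnorm runif rgamma rbinom rlnorm sd
#'   pt qt glm binomial predict complete.cases setNames p.adjust wilcox.test
#'   fisher.test chisq.test var
#' @importFrom utils combn write.table read.delim head
#' @import data.table
NULL

# Derive a reproducible sub-seed from a master seed and a sequence of labels.
# Polynomial string hash over the labels, folded into [1, 2^31 - 2] so it is
# always a valid 32-bit seed. Stable across platforms (pure integer-free
# double arithmetic below 2^53).
subseed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "\r")
  h <- 5381
  for (code in utf8ToInt(labels)) {
    h <- (h * 33 + code) %% 2147483629
  }
  as.integer(h + 1)
}

# Run code with a temporary RNG state seeded at `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_fraction <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)

# Canonical covariate column names used throughout the pipeline.
covariate_names <- function() {
  c("age", "bmi", "fiber", "female", "nhw", "pet", "smoker", "abx")
}

strata_labels <- function() c(secure = 0, insecure = 1)

stratum_value <- function(stratum) {
  if (is.numeric(stratum) && stratum %in% c(0, 1)) return(as.integer(stratum))
  lv <- strata_labels()
  if (!stratum %in% names(lv)) {
    stopf("unknown stratum '%s' (expected 'secure' or 'insecure')", stratum)
  }
  unname(lv[[stratum]])
}

stratum_label <- function(value) names(strata_labels())[match(value, strata_labels())]
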