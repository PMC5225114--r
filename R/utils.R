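#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile rnorm runif rbinom sd var predict setNames
#' @importFrom utils head
NULL

# Canonical names of the 16 co-registered parameter maps, grouped by modality.
MAP_NAMES <- c(
  "T1", "T1pc", "T2", "FLAIR",                    # conventional MRI
  "CBV", "CBF", "MTT", "TTP", "R2",               # perfusion MRI
  "FA", "MD", "AD", "RD", "MK", "AK", "RK"        # diffusion kurtosis MRI
)

MODALITY_SETS <- list(
  cmri = c("T1", "T1pc", "T2", "FLAIR"),
  pwi  = c("CBV", "CBF", "MTT", "TTP", "R2"),
  dki  = c("FA", "MD", "AD", "RD", "MK", "AK", "RK"),
  cpd  = c("T1", "T1pc", "T2", "FLAIR", "CBV", "CBF", "MTT", "TTP", "R2",
           "FA", "MD", "AD", "RD", "MK", "AK", "RK")
)

DELINEATIONS <- c("total", "cer_ner")
CLASS_LEVELS <- c("progressive", "responsive")

#' Map names for a modality dataset
#'
#' The four modality datasets used throughout the pipeline: conventional MRI
#' (`cmri`: T1, T1pc, T2, FLAIR), perfusion (`pwi`: CBV, CBF, MTT, TTP, R2),
#' diffusion kurtosis (`dki`: FA, MD, AD, RD, MK, AK, RK) and all sixteen maps
#' combined (`cpd`).
#'
#' @param modality One of `"cmri"`, `"pwi"`, `"dki"`, `"cpd"`.
#' @return Character vector of map names.
#' @export
modality_maps <- function(modality) {
  modality <- match.arg(modality, names(MODALITY_SETS))
  MODALITY_SETS[[modality]]
}

# Deterministic 32-bit seed derived from a master seed and a character tag.
# Used to fan one master seed out to independent per-fold / per-cell streams.
derive_seed <- function(master_seed, tag) {
  h <- as.double(master_seed %% 2147483647L)
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
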