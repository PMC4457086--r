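#' Strain simulation profiles
#'
#' A strain profile bundles the stochastic parameters of the synthetic
#' elongation-complex read generator for one genetic background. Two
#' presets are provided: `"WT"` (Gre factors present, backtracked
#' complexes rescued, transcription errors proofread) and `"dGreAB"`
#' (GreA/GreB deletion: deeper backtracking and uncorrected 3'-end
#' misincorporations).
#'
#' Translocation states are encoded as `post`, `pre`, `bt1`, `bt2`,
#' `bt3` (1- to 3-bp backtracked). The RNase-protected fragment length
#' is `14 + t` nucleotides where `t = 0` (post-translocated), `1`
#' (pre-translocated) or `1 + b` for a `b`-bp backtracked complex.
#'
#' The background state distributions differ between the presets so
#' that the genome-wide modal protected length is 16 nt for `"WT"` and
#' 18 nt for `"dGreAB"`, matching the observed strain contrast in
#' RNase-footprinted nascent transcripts. Planted pause sites use their
#' own state distributions (see [plant_pauses()]).
#'
#' @param name `"WT"`, `"dGreAB"` or `"custom"`.
#' @param background_state_distribution named probabilities over
#'   `c("post","pre","bt1","bt2","bt3")`; must sum to 1. Defaults depend
#'   on `name`.
#' @param default_misincorporation_rate probability that a backtracked
#'   read whose reference 3' base is G carries a G-to-A
#'   misincorporation at its 3' end. Default 0 for WT, 8e-3 for dGreAB.
#' @param rnase_t1_bias probability in `[0,1]` that the 5' trim point of
#'   a read is shifted up to 2 nt upstream so that the genomic base
#'   immediately 5' of the read start is G (RNase T1 cuts GpN bonds).
#' @param sequencing_error_rate per-base uniform substitution rate of
#'   the sequencing channel (default 1e-4).
#' @param p_untrimmed probability that a read keeps untrimmed 5' excess
#'   RNA (3-12 extra nt, capped at a 30-nt read), producing the long
#'   (>= 21 nt) reads that lack an RNase T1 signature.
#' @param p_initiation probability that a read derives from an
#'   initiation complex: a sub-footprint 6-13 nt read whose 5' end sits
#'   at a transcription start site.
#' @param strain_jitter_sd standard deviation (log scale) of the
#'   per-gene expression perturbation applied independently per strain,
#'   emulating biological variability between cultures.
#' @return an object of class `strain_profile`.
#' @export
strain_profile <- function(name = c("WT", "dGreAB", "custom"),
                           background_state_distribution = NULL,
                           default_misincorporation_rate = NULL,
                           rnase_t1_bias = 0.5,
                           sequencing_error_rate = 1e-4,
                           p_untrimmed = 0.15,
                           p_initiation = 0.08,
                           strain_jitter_sd = 0.3) {
  name <- match.arg(name)
  if (is.null(background_state_distribution)) {
    background_state_distribution <- switch(name,
      WT     = c(post = 0.10, pre = 0.20, bt1 = 0.45, bt2 = 0.15, bt3 = 0.10),
      dGreAB = c(post = 0.05, pre = 0.10, bt1 = 0.15, bt2 = 0.25, bt3 = 0.45),
      custom = c(post = 0.45, pre = 0.45, bt1 = 0.10, bt2 = 0.00, bt3 = 0.00)
    )
  }
  if (is.null(default_misincorporation_rate)) {
    default_misincorporation_rate <- if (name == "dGreAB") 8e-3 else 0
  }
  check_state_distribution(background_state_distribution)
  stopifnot(rnase_t1_bias >= 0, rnase_t1_bias <= 1,
            sequencing_error_rate >= 0, sequencing_error_rate <= 1,
            default_misincorporation_rate >= 0,
            default_misincorporation_rate <= 1,
            p_untrimmed >= 0, p_untrimmed <= 1,
            p_initiation >= 0, p_initiation <= 1)
  structure(list(
    name = name,
    background_state_distribution = background_state_distribution,
    default_misincorporation_rate = default_misincorporation_rate,
    rnase_t1_bias = rnase_t1_bias,
    sequencing_error_rate = sequencing_error_rate,
    p_untrimmed = p_untrimmed,
    p_initiation = p_initiation,
    strain_jitter_sd = strain_jitter_sd
  ), class = "strain_profile")
}

STATE_NAMES <- c("post", "pre", "bt1", "bt2", "bt3")

# Planted-site state distributions per motif class (occupancies at
# strong pause elements, as opposed to the elongation background).
planted_state_distribution <- function(motif_class) {
  switch(motif_class,
    WT_PIE   = c(post = 0.15, pre = 0.60, bt1 = 0.15, bt2 = 0.05, bt3 = 0.05),
    dGre_PIE = c(post = 0.05, pre = 0.15, bt1 = 0.20, bt2 = 0.25, bt3 = 0.35),
    none     = c(post = 0.30, pre = 0.40, bt1 = 0.15, bt2 = 0.10, bt3 = 0.05)
  )
}

check_state_distribution <- function(p) {
  if (!all(STATE_NAMES %in% names(p))) {
    stop("state distribution must be named over ",
         paste(STATE_NAMES, collapse = ", "), call. = FALSE)
  }
  p <- p[STATE_NAMES]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("state distribution must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(p)
}

# Protected fragment length for a state label: 14 + t, with
# t = 0 (post), 1 (pre), 1 + b (b-bp backtracked).
state_protected_length <- function(state) {
  t <- c(post = 0L, pre = 1L, bt1 = 2L, bt2 = 3L, bt3 = 4L)[state]
  unname(14L + t)
}

#' @export
print.strain_profile <- function(x, ...) {
  cat("<strain_profile>", x$name, "\n")
  cat("  background states:",
      paste(sprintf("%s=%.2f", names(x$background_state_distribution),
                    x$background_state_distribution), collapse = " "), "\n")
  cat(sprintf("  misincorporation=%g rnase_t1_bias=%g seq_error=%g\n",
              x$default_misincorporation_rate, x$rnase_t1_bias,
              x$sequencing_error_rate))
  invisible(x)
}
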