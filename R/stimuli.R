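# Multi-cue stimulus design: 16 art pieces, each the combination of four
# binary cues, each carrying a fixed probability of receiving a "high"
# rating from the critic. Probabilities between 0.4 and 0.6 define the
# ambiguous (weakly predictive) condition; the rest are unambiguous.

# design columns C1..C4 and p(high) for the 16 stimuli
multicue_design <- function() {
  tab <- data.frame(
    stimulus_id = 1:16,
    C1 = c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 0, 1, 0, 0, 0, 1),
    C2 = c(0, 0, 0, 1, 0, 0, 0, 1, 1, 1, 0, 0, 1, 1, 1, 1),
    C3 = c(0, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 1, 1, 0, 1, 1),
    C4 = c(0, 1, 0, 0, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1),
    p_high = c(0.100, 0.133, 0.166, 0.200, 0.400, 0.429, 0.458, 0.487,
               0.516, 0.545, 0.574, 0.600, 0.800, 0.833, 0.866, 0.900)
  )
  tab$condition <- ifelse(tab$p_high >= 0.4 & tab$p_high <= 0.6,
                          "ambiguous", "unambiguous")
  tab
}

#' Build the 16 multi-cue stimuli
#'
#' Returns the full multi-cue stimulus set: the Cartesian product of four
#' binary cues, each stimulus with its fixed probability of receiving a
#' high rating (`p_high`) and its condition label (`"ambiguous"` when
#' `p_high` lies in \[0.4, 0.6\], `"unambiguous"` otherwise). The
#' design-to-physical cue mapping is randomised across participants in the
#' task; `cue_assignment` expresses that mapping. Relabelling the physical
#' cues permutes only the presentation order of the bits in `cue_levels`;
#' the mapping from design columns to `p_high` never changes.
#'
#' @param cue_assignment Permutation of `1:4`; element `j` gives the design
#'   column presented as physical cue `j`.
#' @return A data frame with 16 rows and columns `stimulus_id`, `C1`--`C4`
#'   (design cue levels), `cue_levels` (physical-order bits, pipe
#'   separated), `p_high`, `condition`.
#' @examples
#' stim <- build_multicue_stimuli()
#' stim[stim$stimulus_id == 16, c("cue_levels", "p_high", "condition")]
#' @export
build_multicue_stimuli <- function(cue_assignment = 1:4) {
  if (length(cue_assignment) != 4L || !setequal(cue_assignment, 1:4)) {
    stop_invalid("`cue_assignment` must be a permutation of 1:4")
  }
  cue_assignment <- as.integer(cue_assignment)
  tab <- multicue_design()
  bits <- as.matrix(tab[, c("C1", "C2", "C3", "C4")])
  phys <- bits[, cue_assignment, drop = FALSE]
  tab$cue_levels <- apply(phys, 1L, paste, collapse = "|")
  tab[, c("stimulus_id", "C1", "C2", "C3", "C4", "cue_levels",
          "p_high", "condition")]
}
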