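#' Health states and strategies
#'
#' The model partitions post-stroke disability into five health states based
#' on the modified Rankin Scale (mRS): `MRS01` (no or minimal symptoms,
#' mRS 0-1), `MRS23` (slight to moderate disability, mRS 2-3), `MRS4`
#' (moderately severe disability), `MRS5` (severe disability, bedridden), and
#' `DEAD` (mRS 6). `DEAD` is absorbing. Two triage strategies are compared:
#' direct transfer to the angiography suite (`DTAS`) and initial transfer to
#' the emergency room (`ITER`).
#'
#' @return `health_states()` and `living_states()` return character vectors of
#'   state labels; `strategies()` returns the two strategy labels.
#' @export
#' @examples
#' health_states()
#' strategies()
health_states <- function() c("MRS01", "MRS23", "MRS4", "MRS5", "DEAD")

#' @rdname health_states
#' @export
living_states <- function() c("MRS01", "MRS23", "MRS4", "MRS5")

#' @rdname health_states
#' @export
strategies <- function() c("DTAS", "ITER")

# internal: number of states
.n_states <- 5L

.match_strategy <- function(strategy) {
  match.arg(toupper(strategy), strategies())
}

.match_state <- function(state) {
  match.arg(toupper(state), health_states())
}
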