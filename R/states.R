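#' State space of the disability process
#'
#' The model uses four states: 0 = no disability, 1 = mild disability,
#' 2 = severe disability, 3 = death. Death is the single absorbing state;
#' states 0-2 are the living states.
#'
#' @return A list with integer vectors `states`, `living`, the scalar
#'   `death`, and a character vector of `labels` indexed by `state + 1`.
#' @examples
#' state_space()$labels
#' @export
state_space <- function() {
  list(
    states = 0:3,
    living = 0:2,
    death = 3L,
    labels = c("no_disability", "mild_disability", "severe_disability", "death")
  )
}

state_label <- function(state) state_space()$labels[state + 1L]
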