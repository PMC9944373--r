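#' The worked repeated-event example tree
#'
#' `TOP = AND(OR(A, B), OR(B, C))` with every leaf probability 0.1. `B`
#' feeds both OR branches, so the tree has a repeated event: bottom-up
#' gate combination is no longer exact and the engine must factor on `B`.
#' Its minimal cut sets are `{B}` and `{A, C}`; the exact top probability
#' is `P(B or (A and C)) = 0.1 + 0.01 - 0.001 = 0.109`, the rare-event
#' sum is 0.11 and `FV(B) = 0.1 / 0.109`.
#'
#' @param p leaf probability shared by A, B, C (default 0.1).
#' @return A `fault_tree`.
#' @export
worked_example_tree <- function(p = 0.1) {
  mk <- function(id) basic_event(
    id, sources = list(source_estimate(p, "literature", "worked-example")))
  fault_tree(
    name = "worked-example", top = "TOP",
    gates = list(gate("TOP", "AND", c("G1", "G2")),
                 gate("G1", "OR", c("A", "B")),
                 gate("G2", "OR", c("B", "C"))),
    events = list(mk("A"), mk("B"), mk("C")))
}
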