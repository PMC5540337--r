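#' Stochastic entry simulator
#'
#' Monte-Carlo realisation of the process the deterministic model
#' averages: for each hole, mosquito appearances in its 30 cm x 30 cm
#' neighbourhood arrive as a homogeneous Poisson process at the hole's
#' functional-area rate (times mosquitoes and hours), each appearance
#' independently becomes an encounter with the hole's encounter
#' probability, and each encounter a passage with its passage
#' probability. The expected total equals
#' `assess_net(...)$total_entries_per_hour * hours * n_mosquitoes`, which
#' makes the simulator an independent check on the rate arithmetic.
#'
#' Appearance streams are homogeneous in time; real activity fluctuates
#' within a session, but only hourly expectations enter the model, for
#' which the homogeneous process is sufficient.
#'
#' @param holes List of [hole()] objects.
#' @param params A [species_params()] object.
#' @param hours Simulated exposure (replicate-hours).
#' @param n_mosquitoes Number of mosquitoes attacking throughout.
#' @param seed Integer seed, or `NULL` to continue the RNG stream.
#' @return Integer total entry count, with attribute `per_hole` (counts
#'   by hole) and `expected` (the deterministic expectation).
#' @export
#' @examples
#' h <- hole("r", "FA1", hole_shape("circle", diameter = 25))
#' simulate_entries(list(h), hours = 100, seed = 1)
simulate_entries <- function(holes, params = an_gambiae_params(),
                             hours = 1, n_mosquitoes = 1, seed = NULL) {
  stopifnot(hours > 0, n_mosquitoes >= 0)
  if (!is.null(seed)) set.seed(seed)
  per_hole <- vapply(holes, function(h) {
    r <- hole_entry_rate(h, params)
    appearances <- rpois(1, r$appearances_per_hour * hours * n_mosquitoes)
    encounters <- rbinom(1, appearances, r$encounter_prob)
    rbinom(1, encounters, r$passage_prob)
  }, numeric(1))
  total <- sum(per_hole)
  expected <- sum(vapply(holes, function(h) {
    hole_entry_rate(h, params)$entries_per_hour
  }, numeric(1))) * hours * n_mosquitoes
  structure(total, per_hole = per_hole, expected = expected)
}
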