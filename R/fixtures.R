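# Hand-built fixture trees with known crown nodes -----------------------
#
# Each fixture is constructed in code; the same trees ship as plain Newick
# under inst/extdata with a side-car table (fixtures.csv) of tip counts and
# hand-computed crown times, so tests can cross-check the in-code builder
# against the serialized catalogue.

fixture_builders <- list(
  # both origin lineages extant: crown at the origin, time 0
  two_tip_extant = function() {
    bd_tree(birth = c(0, 0), death = c(NA, NA), parent = c(NA, NA),
            extant = c(TRUE, TRUE), present = 10, labels = c("A", "B"))
  },
  # one origin lineage wholly extinct; the surviving side splits at t = 4
  one_side_extinct = function() {
    bd_tree(birth  = c(0, 0, 4, 4),
            death  = c(4, 3, NA, NA),
            parent = c(NA, NA, 1, 1),
            extant = c(FALSE, FALSE, TRUE, TRUE),
            present = 10, labels = c("P", "Q", "A", "B"))
  },
  # 5 tips (3 extant A,B,C; 2 extinct D,Q); crown = split of P at t = 2
  five_tip_mixed = function() {
    bd_tree(birth  = c(0, 0, 2, 2, 5, 5, 7, 7),
            death  = c(2, 6, 5, 7, NA, NA, NA, 9),
            parent = c(NA, NA, 1, 1, 3, 3, 4, 4),
            extant = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
            present = 10,
            labels = c("P", "Q", "P1", "P2", "A", "B", "C", "D"))
  },
  # exactly one extant tip: crown group undefined
  single_survivor = function() {
    bd_tree(birth = c(0, 0), death = c(NA, 3), parent = c(NA, NA),
            extant = c(TRUE, FALSE), present = 8, labels = c("A", "B"))
  },
  # extant tips on both sides of the origin despite an extinct offshoot
  crown_at_origin = function() {
    bd_tree(birth  = c(0, 0, 4, 4),
            death  = c(4, NA, NA, 6),
            parent = c(NA, NA, 1, 1),
            extant = c(FALSE, TRUE, TRUE, FALSE),
            present = 10, labels = c("P", "R", "A", "B"))
  }
)

#' Build a named fixture tree
#'
#' Deterministic small trees with documented crown nodes, used throughout the
#' test suite and handy for exploring the crown statistics by hand.
#'
#' @param name One of `"two_tip_extant"`, `"one_side_extinct"`,
#'   `"five_tip_mixed"`, `"single_survivor"`, `"crown_at_origin"`.
#' @return A [bd_tree()].
#' @seealso [fixture_catalogue()] for the documented properties of each tree.
#' @export
#' @examples
#' crown_fraction(make_fixture("five_tip_mixed"))
make_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(fixture_builders))
    stop_crownsim(sprintf("unknown fixture '%s'; valid names: %s",
                          paste(name, collapse = ","),
                          paste(names(fixture_builders), collapse = ", ")),
                  "crownsim_bad_fixture")
  fixture_builders[[name]]()
}

#' Catalogue of fixture trees
#'
#' @return A data frame with one row per fixture: `name`, `file` (the Newick
#'   file under `inst/extdata`), `n_tips`, `n_extant`, hand-computed
#'   `crown_time` (`NA` where the crown group is undefined) and
#'   `present`.
#' @export
fixture_catalogue <- function() {
  data.frame(
    name = c("two_tip_extant", "one_side_extinct", "five_tip_mixed",
             "single_survivor", "crown_at_origin"),
    file = paste0(c("two_tip_extant", "one_side_extinct", "five_tip_mixed",
                    "single_survivor", "crown_at_origin"), ".nwk"),
    n_tips = c(2L, 3L, 5L, 2L, 3L),
    n_extant = c(2L, 2L, 3L, 1L, 2L),
    crown_time = c(0, 4, 2, NA, 0),
    present = c(10, 10, 10, 8, 10),
    stringsAsFactors = FALSE)
}
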