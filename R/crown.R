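# Crown-group emergence statistics ---------------------------------------

# flag lineages with at least one extant descendant (themselves included);
# relies on topological order (parent index < child index)
extant_desc_flags <- function(tree) {
  f <- tree$extant
  p <- tree$parent
  for (i in rev(seq_along(f)))
    if (f[i] && !is.na(p[i])) f[p[i]] <- TRUE
  f
}

#' Locate the crown node of a tree
#'
#' The crown node is the most recent node ancestral to every lineage alive at
#' the present: the speciation event ending the deepest lineage whose two
#' daughter subtrees both contain extant descendants.  When extant tips
#' descend from both origin lineages, the crown node is the initial split
#' itself, reported as `"origin"` (time 0).
#'
#' @param tree A [bd_tree()] with at least two extant lineages.
#' @return A lineage index (the lineage whose terminal speciation is the
#'   crown divergence) or the string `"origin"`.
#' @seealso [mrca_oracle()] for the brute-force equivalent, [crown_time()].
#' @export
crown_node <- function(tree) {
  if (n_extant(tree) < 2L)
    stop_crownsim(
      "crown group undefined: fewer than 2 extant lineages",
      "crownsim_undefined_crown")
  f <- extant_desc_flags(tree)
  roots <- which(is.na(tree$parent))
  if (f[roots[1]] && f[roots[2]]) return("origin")
  n <- n_lineages(tree)
  nkf <- tabulate(tree$parent[f & !is.na(tree$parent)], n)
  cand <- which(nkf == 2L)
  cand[which.min(tree$birth[cand])]
}

#' Crown emergence time and fraction of total-group duration
#'
#' `crown_time()` is the time (from the origin at 0) of the crown node;
#' `crown_fraction()` additionally expresses it as a fraction of the
#' total-group duration `T`, the scale on which results are reported.
#' Fractions use exact node times, never re-derived from Newick rounding.
#'
#' @param tree A [bd_tree()] with >= 2 extant lineages.
#' @param tree_id Optional identifier carried into the record.
#' @return `crown_time()`: a time in `[0, T]`.  `crown_fraction()`: a
#'   one-row data frame with `tree_id`, `n_extant`, `crown_time` and
#'   `fraction` (`crown_time / T`, in `[0, 1]`; 0 exactly when both origin
#'   lineages have extant descendants).
#' @export
#' @examples
#' crown_fraction(make_fixture("five_tip_mixed"))  # fraction 0.2
crown_time <- function(tree) {
  node_time(tree, crown_node(tree))
}

#' @rdname crown_time
#' @export
crown_fraction <- function(tree, tree_id = NA_integer_) {
  ct <- crown_time(tree)
  data.frame(tree_id = tree_id, n_extant = n_extant(tree),
             crown_time = ct, fraction = ct / tree$present)
}

#' Crown records for a survival-conditioned sample
#'
#' @param sample A `bd_sample` from [simulate_surviving()].
#' @return A data frame with one [crown_fraction()] row per surviving tree.
#' @export
crown_records <- function(sample) {
  stopifnot(inherits(sample, "bd_sample"))
  out <- mapply(crown_fraction, sample$trees, sample$tree_ids,
                SIMPLIFY = FALSE)
  do.call(rbind, out)
}

#' Summarize crown fractions for one rate condition
#'
#' Mean and sample (n - 1) standard deviation of the crown emergence
#' fraction across surviving trees, plus the +/- 2 s.d. interval
#' conventionally drawn as error bars.
#'
#' @param records Data frame of [crown_fraction()] rows (>= 2).
#' @param speciation,extinction The condition's rates `S` and `E`.
#' @param duration The condition's duration `T`.
#' @return One-row data frame: `S`, `E`, `D = S - E`, `T`, `n`,
#'   `mean_fraction`, `sd_fraction`, `lo_2sd`, `hi_2sd`.
#' @export
summarize_condition <- function(records, speciation, extinction, duration) {
  if (!is.data.frame(records) || nrow(records) < 2L)
    stop_crownsim("at least 2 crown records are needed to summarize a condition",
                  "crownsim_too_few_records")
  m <- mean(records$fraction)
  s <- sd(records$fraction)
  data.frame(S = speciation, E = extinction, D = speciation - extinction,
             T = duration, n = nrow(records),
             mean_fraction = m, sd_fraction = s,
             lo_2sd = m - 2 * s, hi_2sd = m + 2 * s)
}
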