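# Tree data model -------------------------------------------------------
#
# A bd_tree stores one lineage per row of four parallel vectors.  Lineage 1
# and 2 are the origin pair born at time 0 (the initial split of the total
# group from its sister is the "origin", a virtual degree-two root).  A
# speciating lineage terminates and is replaced by two daughters, so every
# lineage has either 0 or 2 children and internal "nodes" are speciation
# events located at the death time of the parent lineage.  Lineages are
# stored in topological order: parent index < child index.

#' Construct a birth-death tree object
#'
#' Low-level constructor for the `bd_tree` class.  Most users will obtain
#' trees from [simulate_tree()], [read_newick()] or [make_fixture()] instead.
#'
#' @param birth Numeric vector of lineage birth times (time units from the
#'   origin at 0).
#' @param death Numeric vector of lineage termination times; `NA` for
#'   lineages alive at the present.  A lineage with children dies at the
#'   birth time of its children (bifurcating speciation, no budding).
#' @param parent Integer vector of parent lineage indices; `NA` for the two
#'   origin lineages.
#' @param extant Logical vector; extant status is explicit, never inferred
#'   from comparing times with the present.
#' @param present Present time `T` (> 0); the tree spans `[0, present]`.
#' @param labels Optional character vector of lineage labels; defaults to
#'   `t1 ... tn`.
#' @param validate If `TRUE`, check the class invariants.
#'
#' @return An object of class `bd_tree`: a list with elements `birth`,
#'   `death`, `parent`, `extant`, `present`, `labels`.
#' @seealso [simulate_tree()], [read_newick()], [make_fixture()]
#' @export
bd_tree <- function(birth, death, parent, extant, present,
                    labels = NULL, validate = TRUE) {
  n <- length(birth)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  x <- structure(
    list(birth = as.numeric(birth), death = as.numeric(death),
         parent = as.integer(parent), extant = as.logical(extant),
         present = as.numeric(present), labels = as.character(labels)),
    class = "bd_tree")
  if (validate) validate_bd_tree(x)
  x
}

stop_crownsim <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "crownsim_error")))
}

validate_bd_tree <- function(x, tol = 1e-9) {
  n <- length(x$birth)
  if (length(x$death) != n || length(x$parent) != n ||
      length(x$extant) != n || length(x$labels) != n)
    stop_crownsim("lineage vectors have unequal lengths", "crownsim_invalid_tree")
  if (!is.finite(x$present) || x$present <= 0)
    stop_crownsim("present time must be a positive number", "crownsim_invalid_tree")
  roots <- which(is.na(x$parent))
  if (length(roots) != 2L || any(x$birth[roots] != 0))
    stop_crownsim("a tree must have exactly two origin lineages born at time 0",
                  "crownsim_invalid_tree")
  if (n > 2L) {
    ip <- x$parent[-roots]
    if (any(is.na(ip)) || any(ip >= seq_len(n)[-roots]) || any(ip < 1L))
      stop_crownsim("lineages must be stored in topological order (parent < child)",
                    "crownsim_invalid_tree")
  }
  nk <- tabulate(x$parent[!is.na(x$parent)], n)
  if (!all(nk %in% c(0L, 2L)))
    stop_crownsim("every lineage must have 0 or 2 children (bifurcation only)",
                  "crownsim_invalid_tree")
  if (any(x$extant & nk > 0L))
    stop_crownsim("an extant lineage cannot have children", "crownsim_invalid_tree")
  if (any(x$extant & !is.na(x$death)))
    stop_crownsim("extant lineages must have NA death time", "crownsim_invalid_tree")
  dead <- !x$extant
  if (any(is.na(x$death[dead])))
    stop_crownsim("non-extant lineages need a death time", "crownsim_invalid_tree")
  if (any(x$death[dead] < x$birth[dead] - tol) ||
      any(x$death[dead] > x$present + tol))
    stop_crownsim("death times must lie in [birth, present]", "crownsim_invalid_tree")
  has_kids <- nk > 0L
  if (any(has_kids)) {
    kb <- x$birth[!is.na(x$parent)]
    kp <- x$parent[!is.na(x$parent)]
    if (any(abs(kb - x$death[kp]) > tol))
      stop_crownsim("children must be born at their parent's death time",
                    "crownsim_invalid_tree")
  }
  if (any(x$birth > x$present + tol))
    stop_crownsim("birth times cannot exceed the present", "crownsim_invalid_tree")
  invisible(x)
}

#' Number of lineages / extant tips in a tree
#'
#' @param tree A `bd_tree`.
#' @return `n_lineages()`: total lineage count; `n_extant()`: number of
#'   lineages alive at the present.
#' @export
n_lineages <- function(tree) length(tree$birth)

#' @rdname n_lineages
#' @export
n_extant <- function(tree) sum(tree$extant)

# end of a lineage on the time axis: death time, or the present if extant
end_time <- function(tree) ifelse(tree$extant, tree$present, tree$death)

# indices of childless lineages (tips of the drawn tree)
tip_ids <- function(tree) {
  which(tabulate(tree$parent[!is.na(tree$parent)], n_lineages(tree)) == 0L)
}

#' @export
print.bd_tree <- function(x, ...) {
  cat(sprintf("bd_tree: %d lineages (%d tips, %d extant), present time T = %g\n",
              n_lineages(x), length(tip_ids(x)), n_extant(x), x$present))
  invisible(x)
}

# Conversion to ape ------------------------------------------------------

#' Convert a bd_tree to an ape "phylo" object
#'
#' The origin becomes the (degree-two) root node at time 0; each lineage
#' becomes one edge whose length is the lineage's lifespan.  Extant status is
#' carried in tip labels via a `|A` (alive) / `|X` (extinct) suffix when
#' `status = TRUE`.
#'
#' @param x A `bd_tree`.
#' @param status Append the extant-status suffix to tip labels.
#' @param ... Ignored.
#' @return An object of class `phylo`.
#' @importFrom ape as.phylo
#' @export
as.phylo.bd_tree <- function(x, status = TRUE, ...) {
  n <- n_lineages(x)
  nk <- tabulate(x$parent[!is.na(x$parent)], n)
  is_tip <- nk == 0L
  ntip <- sum(is_tip)
  node_of <- integer(n)
  node_of[is_tip] <- seq_len(ntip)
  node_of[!is_tip] <- ntip + 1L + seq_len(n - ntip)
  parent_node <- rep(ntip + 1L, n)              # origin = root node
  ok <- !is.na(x$parent)
  parent_node[ok] <- node_of[x$parent[ok]]
  lab <- x$labels[is_tip]
  if (status) lab <- paste0(lab, ifelse(x$extant[is_tip], "|A", "|X"))
  phy <- list(edge = cbind(parent_node, node_of, deparse.level = 0),
              edge.length = end_time(x) - x$birth,
              tip.label = lab,
              Nnode = n - ntip + 1L)
  class(phy) <- "phylo"
  phy
}

# Newick I/O -------------------------------------------------------------

#' Read a time-calibrated Newick tree with extant/extinct tip flags
#'
#' Parses a Newick string (or file) whose branch lengths are forward time
#' durations and whose tip labels end in `|A` (alive at the present) or `|X`
#' (extinct).  The tree must be strictly bifurcating and begin at the initial
#' split of the two origin lineages (no root edge).  Node times are
#' reconstructed by summing branch lengths from the origin at time 0.
#'
#' @param text A Newick string (one tree).
#' @param file Alternatively, path to a file whose first line is the tree.
#' @param present_time Optional present time `T`; defaults to the depth of
#'   the extant tips (which must all be equidistant from the origin), or the
#'   deepest tip when no tip is extant.
#' @return A [bd_tree()].
#' @importFrom ape read.tree node.depth.edgelength
#' @export
#' @examples
#' tr <- read_newick("((A|A:5,B|A:5):5,C|A:10);")
#' crown_time(tr)   # 0: living tips descend from both origin lineages
read_newick <- function(text = NULL, file = NULL, present_time = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop_crownsim("supply `text` or `file`", "crownsim_parse")
    text <- readLines(file, warn = FALSE)
    text <- text[nzchar(trimws(text))][1]
  }
  txt <- trimws(text)
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop_crownsim(sprintf("malformed Newick: unbalanced ')' at character %d",
                          which(depth < 0)[1]), "crownsim_parse")
  if (depth[length(depth)] != 0)
    stop_crownsim(sprintf("malformed Newick: unbalanced '(' opened at character %d",
                          which(depth == max(depth))[1]), "crownsim_parse")
  neg <- regexpr(":\\s*-", txt)
  if (neg > 0)
    stop_crownsim(sprintf("negative branch length at character %d", as.integer(neg)),
                  "crownsim_invalid_tree")
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(phy) || is.null(phy$edge))
    stop_crownsim("malformed Newick: ape could not parse the string", "crownsim_parse")
  if (is.null(phy$edge.length))
    stop_crownsim("branch lengths are mandatory", "crownsim_parse")
  if (!is.null(phy$root.edge) && phy$root.edge != 0)
    stop_crownsim("trees must begin at the initial split (no root edge allowed)",
                  "crownsim_parse")
  ntip <- length(phy$tip.label)
  kids <- tabulate(phy$edge[, 1], ntip + phy$Nnode)
  if (any(kids[(ntip + 1):(ntip + phy$Nnode)] != 2L))
    stop_crownsim("tree must be strictly bifurcating with a degree-two root",
                  "crownsim_parse")
  has_status <- grepl("\\|[AX]$", phy$tip.label)
  if (!all(has_status))
    stop_crownsim(sprintf("tip '%s' lacks the |A / |X status suffix",
                          phy$tip.label[!has_status][1]), "crownsim_parse")
  tip_extant <- grepl("\\|A$", phy$tip.label)
  tip_lab <- sub("\\|[AX]$", "", phy$tip.label)

  dep <- ape::node.depth.edgelength(phy)
  if (is.null(present_time)) {
    if (any(tip_extant)) {
      dext <- dep[seq_len(ntip)][tip_extant]
      if (diff(range(dext)) > 1e-9)
        stop_crownsim("extant tips are not equidistant from the origin",
                      "crownsim_invalid_tree")
      present_time <- max(dext)
    } else {
      present_time <- max(dep[seq_len(ntip)])
    }
  }
  if (any(dep[seq_len(ntip)] > present_time + 1e-9))
    stop_crownsim("a tip lies beyond the present time", "crownsim_invalid_tree")

  # one lineage per edge, in preorder so parent < child
  ord <- order_edges_preorder(phy)
  edge <- phy$edge[ord, , drop = FALSE]
  nlin <- nrow(edge)
  lin_of_node <- integer(ntip + phy$Nnode)
  lin_of_node[edge[, 2]] <- seq_len(nlin)
  root <- ntip + 1L
  parent <- ifelse(edge[, 1] == root, NA_integer_, lin_of_node[edge[, 1]])
  birth <- dep[edge[, 1]]
  endt <- dep[edge[, 2]]
  is_tip <- edge[, 2] <= ntip
  extant <- is_tip & tip_extant[ifelse(is_tip, edge[, 2], 1L)]
  death <- ifelse(extant, NA_real_, endt)
  labels <- ifelse(is_tip, tip_lab[ifelse(is_tip, edge[, 2], 1L)],
                   paste0("n", edge[, 2]))
  bd_tree(birth, death, parent, extant, present_time, labels)
}

# preorder (root-to-tip) ordering of edge rows
order_edges_preorder <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  out <- integer(nrow(phy$edge))
  stack <- rev(kids[[as.character(root)]])
  i <- 0L
  while (length(stack)) {
    e <- stack[length(stack)]
    stack <- stack[-length(stack)]
    i <- i + 1L
    out[i] <- e
    child <- phy$edge[e, 2]
    if (child > ntip) stack <- c(stack, rev(kids[[as.character(child)]]))
  }
  out
}

#' Write a tree as Newick, optionally pruned to the extant lineages
#'
#' Serializes a [bd_tree()] with branch lengths equal to lineage lifespans
#' and `|A` / `|X` status suffixes on tip labels.  With `extant_only = TRUE`
#' extinct lineages are pruned and the resulting unary nodes suppressed while
#' path lengths from the origin are preserved: the distance from the origin
#' to the pruned tree's root is emitted as a Newick root edge.
#'
#' @param tree A `bd_tree`.
#' @param extant_only Prune extinct lineages before writing.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string.
#' @importFrom ape write.tree drop.tip
#' @export
write_newick <- function(tree, extant_only = FALSE, digits = 15) {
  if (!extant_only)
    return(ape::write.tree(as.phylo.bd_tree(tree), digits = digits))
  ne <- n_extant(tree)
  if (ne < 1L)
    stop_crownsim("cannot prune to extant lineages: no lineage is extant",
                  "crownsim_no_extant")
  if (ne == 1L) {
    id <- which(tree$extant)
    return(sprintf("%s|A:%.*g;", tree$labels[id], digits, tree$present))
  }
  phy <- as.phylo.bd_tree(tree)
  drop <- phy$tip.label[grepl("\\|X$", phy$tip.label)]
  if (length(drop) == 0L)
    return(ape::write.tree(phy, digits = digits))
  pruned <- ape::drop.tip(phy, drop)
  # all extant tips sit at the present; the pruned root's distance from the
  # origin is therefore the present minus the pruned tip depth
  tip_depth <- max(ape::node.depth.edgelength(pruned))
  root_edge <- tree$present - tip_depth
  if (root_edge > 1e-9) pruned$root.edge <- root_edge
  ape::write.tree(pruned, digits = digits)
}

# MRCA oracle ------------------------------------------------------------

#' Brute-force most recent common ancestor by path intersection
#'
#' Walks rootward from every queried lineage, intersects the ancestor paths
#' (each path includes the lineage itself), and returns the deepest common
#' lineage — deliberately the slowest, most transparent algorithm, used as
#' the validation oracle for [crown_node()].
#'
#' @param tree A `bd_tree`.
#' @param ids Lineage indices (integer) or tip labels (character), at least
#'   one.  Order is irrelevant.
#' @return The index of the deepest lineage ancestral to (or equal to) all of
#'   `ids`, or the string `"origin"` when the query spans both origin
#'   lineages, in which case the MRCA is the initial split at time 0.
#' @export
mrca_oracle <- function(tree, ids) {
  if (length(ids) == 0L)
    stop_crownsim("`ids` must be nonempty", "crownsim_bad_query")
  if (is.character(ids)) {
    m <- match(ids, tree$labels)
    if (anyNA(m))
      stop_crownsim(sprintf("unknown lineage label '%s'", ids[is.na(m)][1]),
                    "crownsim_bad_query")
    ids <- m
  }
  ids <- as.integer(ids)
  n <- n_lineages(tree)
  if (any(ids < 1L | ids > n))
    stop_crownsim("lineage index out of range", "crownsim_bad_query")
  paths <- lapply(ids, function(i) {
    p <- i
    while (!is.na(tree$parent[p[length(p)]]))
      p <- c(p, tree$parent[p[length(p)]])
    p
  })
  common <- Reduce(intersect, paths)
  if (length(common) == 0L) return("origin")
  common[which.max(tree$birth[common])]
}

#' Time of a node on the tree's forward time axis
#'
#' For a lineage index, the time of the event ending that lineage (its
#' speciation when it has children, its extinction when extinct, or the
#' present when extant); for `"origin"`, time 0 (the initial split).  This is
#' the convention under which the MRCA returned by [mrca_oracle()] or
#' [crown_node()] maps to a divergence time.
#'
#' @param tree A `bd_tree`.
#' @param node A lineage index or the string `"origin"`.
#' @return A time in `[0, present]`.
#' @export
node_time <- function(tree, node) {
  if (identical(node, "origin")) return(0)
  end_time(tree)[as.integer(node)]
}
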