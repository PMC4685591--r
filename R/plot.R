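# Schematic tree figure with the crown clade highlighted -----------------

#' Draw a tree with its crown group shaded
#'
#' Schematic rendering: the full tree (extinct lineages included) is drawn
#' left-to-right from the origin to the present, lineages inside the crown
#' group are shaded grey and thickened, the origin is marked with a star and
#' the crown divergence with a filled circle.
#'
#' @param tree A [bd_tree()] with >= 2 extant lineages.
#' @param path Output file; format chosen by extension (`.png`, `.pdf` or
#'   `.svg`).
#' @param width,height Device size in inches.
#' @param show_tip_labels Draw tip labels (off by default; simulated trees
#'   are dense).
#' @return Invisibly, a list with `path`, `crown_node` and `crown_time`.
#' @export
render_tree_figure <- function(tree, path, width = 7, height = 5,
                               show_tip_labels = n_lineages(tree) <= 32) {
  cn <- crown_node(tree)   # errors for undefined crown before any device opens
  ct <- crown_time(tree)
  n <- n_lineages(tree)
  in_crown <- logical(n)
  if (identical(cn, "origin")) {
    in_crown[] <- TRUE
  } else {
    # crown group = the MRCA split and everything descending from it,
    # i.e. all strict descendants of the crown lineage
    p <- tree$parent
    for (i in seq_len(n))
      if (!is.na(p[i]) && (p[i] == cn || in_crown[p[i]])) in_crown[i] <- TRUE
  }
  phy <- as.phylo.bd_tree(tree)
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         stop_crownsim(sprintf("unsupported figure format '.%s' (use png, pdf or svg)",
                               ext), "crownsim_bad_figure"))
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(phy,
       edge.color = ifelse(in_crown, "grey55", "black"),
       edge.width = ifelse(in_crown, 3, 1.2),
       show.tip.label = show_tip_labels, no.margin = FALSE,
       x.lim = c(0, tree$present * if (show_tip_labels) 1.25 else 1))
  graphics::axis(1, at = pretty(c(0, tree$present)))
  graphics::mtext("time since total-group origin", side = 1, line = 2.2,
                  cex = 0.9)
  ntip <- length(phy$tip.label)
  ape::nodelabels(node = ntip + 1L, pch = 8, cex = 1.4, col = "black")
  if (!identical(cn, "origin")) {
    # the crown lineage's end node is where the crown clade begins
    nk <- tabulate(tree$parent[!is.na(tree$parent)], n)
    is_tip <- nk == 0L
    node_of <- integer(n)
    node_of[is_tip] <- seq_len(sum(is_tip))
    node_of[!is_tip] <- sum(is_tip) + 1L + seq_len(n - sum(is_tip))
    ape::nodelabels(node = node_of[cn], pch = 19, cex = 1.2, col = "grey35")
  }
  graphics::legend("topleft", bty = "n", cex = 0.85,
                   legend = c("crown group", "stem lineages",
                              sprintf("crown emergence at t = %.3g (%.1f%% of T)",
                                      ct, 100 * ct / tree$present)),
                   lwd = c(3, 1.2, NA), col = c("grey55", "black", NA))
  invisible(list(path = path, crown_node = cn, crown_time = ct))
}
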