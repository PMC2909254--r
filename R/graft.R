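#' Genus-specific ITS-to-LSU scale factor
#'
#' The species-level (ITS) trees and the genus-level (LSU) backbone sit on
#' different substitution scales because the two markers evolve at
#' different rates. The scale factor for a genus is estimated by comparing
#' branch lengths separating the ingroup species from a common outgroup:
#' `P_its` is the mean patristic distance from each ingroup tip to the
#' (first) outgroup tip in the unsmoothed ITS tree, `P_lsu` the patristic
#' distance between the genus tip and the outgroup genus tip in the
#' unsmoothed backbone, and `s_g = P_lsu / P_its`.
#'
#' @param its_tree unsmoothed (substitution-scale) species-level tree
#'   containing the ingroup species plus outgroup tip(s).
#' @param backbone unsmoothed genus-level tree whose tips are genera.
#' @param genus,outgroup_genus backbone tip labels.
#' @param outgroup_prefix ITS-tree outgroup tips are identified by this
#'   label prefix (default `"OUT_"`) unless `outgroup_tips` is given.
#' @param outgroup_tips explicit outgroup tip labels in `its_tree`.
#' @param mean_over_outgroups average over all outgroup tips instead of
#'   using the first (default FALSE, for determinism).
#' @return list of class `scale_factor` with `genus`, `s_g`, `P_its`,
#'   `P_lsu`.
#' @export
estimate_scale_factor <- function(its_tree, backbone, genus, outgroup_genus,
                                  outgroup_prefix = "OUT_",
                                  outgroup_tips = NULL,
                                  mean_over_outgroups = FALSE) {
  og <- outgroup_tips %||%
    its_tree$tip.label[startsWith(its_tree$tip.label, outgroup_prefix)]
  if (!length(og))
    stop_ecm("outgroup absent from ITS tree for genus ", genus)
  if (!genus %in% backbone$tip.label)
    stop_ecm("genus ", genus, " absent from backbone")
  if (!outgroup_genus %in% backbone$tip.label)
    stop_ecm("outgroup genus ", outgroup_genus, " absent from backbone")
  ingroup <- setdiff(its_tree$tip.label, og)
  if (!length(ingroup)) stop_ecm("no ingroup tips in ITS tree")
  dm <- patristic_distances(its_tree)
  P_its <- if (mean_over_outgroups) {
    mean(dm[ingroup, og, drop = FALSE])
  } else {
    mean(dm[ingroup, og[1]])
  }
  P_lsu <- patristic_distances(backbone)[genus, outgroup_genus]
  if (P_its <= 0) stop_ecm("non-positive ITS outgroup distance")
  structure(list(genus = genus, s_g = P_lsu / P_its,
                 P_its = P_its, P_lsu = P_lsu),
            class = "scale_factor")
}

#' Build grafting plans for every multi-species genus
#'
#' For genus g the crown fraction is
#' `f_g = (s_g * D_its(g)) / L_lsu(g)`, where `D_its` is the mean
#' ingroup root-to-tip depth of the unsmoothed ITS tree after pruning the
#' outgroup, and `L_lsu` the genus stem length in the unsmoothed backbone.
#' `f_g` is capped at `crown_cap_beta` (with a warning) so that the
#' grafted crown never consumes the whole stem; the grafted crown age is
#' `f_g * a_g` with `a_g` the attachment-node age in the smoothed
#' backbone.
#'
#' @param backbone_subs unsmoothed (substitution) backbone.
#' @param backbone_time smoothed (ultrametric, relative-time) backbone
#'   with the same topology and tip labels.
#' @param its_trees named list (by genus) of unsmoothed ITS trees with
#'   outgroups attached.
#' @param outgroup_map named character vector: genus -> outgroup genus.
#' @param crown_cap_beta cap on `f_g` (default 0.9).
#' @param outgroup_prefix passed to [estimate_scale_factor()].
#' @return named list of plans: `s_g`, `f_g`, `a_g`, `capped`.
#' @export
graft_plan <- function(backbone_subs, backbone_time, its_trees,
                       outgroup_map, crown_cap_beta = 0.9,
                       outgroup_prefix = "OUT_") {
  ages <- node_ages(backbone_time)
  lapply(setNames(names(its_trees), names(its_trees)), function(g) {
    if (is.na(outgroup_map[g]))
      stop_ecm("no outgroup genus mapped for ", g)
    sf <- estimate_scale_factor(its_trees[[g]], backbone_subs, g,
                                unname(outgroup_map[g]),
                                outgroup_prefix = outgroup_prefix)
    og <- its_trees[[g]]$tip.label[
      startsWith(its_trees[[g]]$tip.label, outgroup_prefix)]
    pruned <- ape::drop.tip(its_trees[[g]], og)
    D_its <- mean(node_depths(pruned)[seq_len(ape::Ntip(pruned))])
    tipi <- match(g, backbone_subs$tip.label)
    L_lsu <- backbone_subs$edge.length[backbone_subs$edge[, 2] == tipi]
    tipi_t <- match(g, backbone_time$tip.label)
    a_g <- ages[backbone_time$edge[backbone_time$edge[, 2] == tipi_t, 1]]
    f_g <- sf$s_g * D_its / L_lsu
    capped <- f_g > crown_cap_beta
    if (capped)
      warning("crown fraction for ", g, " (", format(f_g, digits = 4),
              ") capped at ", crown_cap_beta, call. = FALSE)
    list(genus = g, s_g = sf$s_g, P_its = sf$P_its, P_lsu = sf$P_lsu,
         D_its = D_its, L_lsu = L_lsu, a_g = unname(a_g),
         f_g = unname(min(f_g, crown_cap_beta)), capped = capped)
  })
}

#' Graft species-level chronograms onto the genus-level chronogram
#'
#' Each multi-species genus tip of the smoothed backbone is replaced by
#' its species-level crown, rescaled to crown age `f_g * a_g`; the stem
#' branch keeps the remaining `a_g - f_g * a_g` of time, so the output is
#' exactly ultrametric. Genera with a single species are relabelled in
#' place. Species trees must be ultrametric (relative deviation below
#' `tol`) with outgroups already pruned.
#'
#' @param backbone_time smoothed backbone (ultrametric, relative time).
#' @param species_time_trees named list by genus: either a `phylo`
#'   chronogram (several species) or a single species label (character).
#' @param plans plans from [graft_plan()]; required for every
#'   multi-species genus.
#' @param tol relative ultrametricity tolerance for inputs.
#' @return the community supertree (ultrametric, relative time).
#' @export
graft <- function(backbone_time, species_time_trees, plans, tol = 1e-6) {
  out <- backbone_time
  multi <- names(species_time_trees)[
    vapply(species_time_trees, inherits, logical(1), "phylo")]
  missing_plan <- setdiff(multi, names(plans))
  if (length(missing_plan))
    stop_ecm("no graft plan for: ", paste(missing_plan, collapse = ", "))
  for (g in names(species_time_trees)) {
    st <- species_time_trees[[g]]
    if (!inherits(st, "phylo")) {     # single-species genus: relabel
      out$tip.label[out$tip.label == g] <- as.character(st)
      next
    }
    depth <- max(node_depths(st)[seq_len(ape::Ntip(st))])
    if (check_ultrametric(st, tol * depth) > tol * depth)
      stop_ecm("species tree for ", g, " is not ultrametric within tol")
    pl <- plans[[g]]
    crown_age <- pl$f_g * pl$a_g
    st$edge.length <- st$edge.length * (crown_age / depth)
    st$root.edge <- pl$a_g - crown_age
    tipi <- match(g, out$tip.label)
    if (is.na(tipi)) stop_ecm("genus ", g, " absent from backbone")
    # bind.tree merges the tip's edge with the grafted root edge, so the
    # stem must be carried entirely by root.edge
    out$edge.length[out$edge[, 2] == tipi] <- 0
    out <- ape::bind.tree(out, st, where = tipi)
  }
  set_tree_scale(out, "relative_time")
}

#' Prune a supertree back to one representative per genus
#'
#' Validation helper: keeps one tip per genus (the first in tip order, or
#' a chosen representative), relabels it with the genus, and returns the
#' reduced tree for topological comparison against the backbone.
#'
#' @param supertree grafted supertree.
#' @param genus_map named character vector: tip label -> genus.
#' @param representatives optional named character vector genus -> tip.
#' @return a `phylo` tree with one tip per genus.
#' @export
prune_to_backbone <- function(supertree, genus_map, representatives = NULL) {
  if (!length(genus_map)) stop_ecm("empty genus_map")
  missing <- setdiff(supertree$tip.label, names(genus_map))
  if (length(missing))
    stop_ecm("tips missing from genus_map: ",
             paste(missing, collapse = ", "))
  gm <- genus_map[supertree$tip.label]
  genera <- unique(unname(gm))
  reps <- if (is.null(representatives)) {
    vapply(genera, function(g) supertree$tip.label[gm == g][1], character(1))
  } else {
    representatives[genera]
  }
  tr <- ape::keep.tip(supertree, unname(reps))
  tr$tip.label <- unname(genus_map[tr$tip.label])
  tr
}
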