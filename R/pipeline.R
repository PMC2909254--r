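fmt_num <- function(x) {
  # fixed %.12g rendering so repeated runs are byte-identical
  if (is.numeric(x)) sprintf("%.12g", x) else x
}

write_tsv <- function(df, path) {
  df[] <- lapply(df, fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full community-phylogenetics pipeline
#'
#' Chains every stage on a synthetic study (or on user-supplied inputs):
#' OTU delimitation of the root-tip ITS sequences at the configured
#' similarity cut-off, genus assignment (unanimous first `min_hits`
#' hits), NPRS smoothing of the genus backbone, scale-factor estimation
#' and grafting of the species-level trees, NRI/NTI against the
#' configured null model, rank/frequency + accumulation + overlap + NMDS
#' (with connectivity filtering), and the per-parameter soil ANOVA.
#'
#' All outputs are written to `out_dir` as plain text with fixed numeric
#' formatting; the JSON log records the seed and every threshold, so a
#' rerun with the same config is byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param synthetic generate the inputs with [generate_study()]
#'   (default). `FALSE` requires `inputs`.
#' @param syn_config a [synthetic_config()] for the synthetic branch; its
#'   seed is overridden by `config$seed`.
#' @param inputs for `synthetic = FALSE`: list with `fasta` (root-tip ITS),
#'   `hits` (taxonomy TSV), `backbone` (Newick, substitutions),
#'   `its_trees` (named Newick paths), `outgroups` (TSV genus/outgroup),
#'   `matrix` (community TSV), `soil` (raw soil TSV).
#' @return invisible list with all stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         synthetic = TRUE, syn_config = NULL,
                         inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  if (synthetic) {
    syn_config <- syn_config %||% synthetic_config()
    syn_config$seed <- config$seed
    study <- generate_study(syn_config)
    records <- study$tip_records
    hits <- study$taxonomy_hits
    backbone_subs <- study$backbone_subs
    its_trees <- study$its_genus_trees
    outgroup_map <- study$outgroup_map
    genus_map <- study$genus_map
    soil_raw <- study$soil_table
  } else {
    if (is.null(inputs))
      stop_ecm("synthetic = FALSE requires an 'inputs' list ",
               "(fasta, hits, backbone, its_trees, outgroups, soil)")
    need <- c("fasta", "hits", "backbone", "its_trees", "outgroups", "soil")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop_ecm("missing pipeline inputs: ", paste(miss, collapse = ", "))
    records <- read_fasta(inputs$fasta)
    hits <- read_taxonomy_hits(inputs$hits)
    backbone_subs <- read_newick(inputs$backbone, scale = "substitutions",
                                 allow_polytomy = TRUE)
    its_trees <- lapply(inputs$its_trees, read_newick,
                        scale = "substitutions", allow_polytomy = TRUE)
    og <- read.delim(inputs$outgroups, colClasses = "character")
    outgroup_map <- setNames(og$outgroup, og$genus)
    genus_map <- NULL
    soil_raw <- read.delim(inputs$soil)
  }

  log <- list(seed = config$seed,
              similarity_threshold = config$similarity_threshold,
              n_null_runs = config$n_null_runs,
              null_model = config$null_model,
              crown_cap_beta = config$crown_cap_beta,
              ordination_k = config$ordination_k,
              min_hits = config$min_hits)

  ## --- OTU delimitation ----------------------------------------------
  otus <- cluster_otus(records, config$similarity_threshold)
  # species identity of each OTU: representative source species (synthetic
  # ids are "<cube>.<species>"); used to tie OTUs to supertree tips
  rep_species <- vapply(otus, function(o)
    sub("^[^.]*\\.", "", o$member_ids[1]), character(1))
  otu_genus <- vapply(seq_along(otus), function(i) {
    h <- hits[[rep_species[i]]] %||% character(0)
    assign_genus(h, config$min_hits)$genus
  }, character(1))
  keep <- !is.na(otu_genus)
  log$n_otus <- length(otus)
  log$n_otus_genus_rejected <- sum(!keep)
  otu_df <- data.frame(
    otu = vapply(otus, `[[`, character(1), "otu_id"),
    species = rep_species, genus = otu_genus,
    n_members = vapply(otus, function(o) length(o$member_ids), integer(1)),
    n_samples = vapply(otus, function(o) length(o$samples), integer(1)),
    retained = keep, stringsAsFactors = FALSE)
  write_tsv(otu_df, file.path(out_dir, "otu_table.tsv"))
  writeLines(paste0(">", otu_df$otu, "\n",
                    vapply(otus, `[[`, character(1), "consensus")),
             file.path(out_dir, "otu_consensus.fasta"))

  # community matrix keyed by representative species of retained OTUs
  meta <- unique(records[, c("sample_id", "forest_id", "habitat")])
  kept <- which(keep)
  x <- vapply(kept, function(i)
    as.integer(meta$sample_id %in% otus[[i]]$samples),
    integer(nrow(meta)))
  dimnames(x) <- list(meta$sample_id, rep_species[kept])
  cm <- community_matrix(x, forest = meta$forest_id, habitat = meta$habitat)
  write_matrix(cm, file.path(out_dir, "community_matrix.tsv"))

  ## --- chronogram + supertree ----------------------------------------
  sm <- nprs_smooth(backbone_subs)
  backbone_time <- sm$tree
  log$nprs_W <- sm$W
  plans <- graft_plan(backbone_subs, backbone_time, its_trees,
                      outgroup_map, config$crown_cap_beta)
  species_time <- lapply(its_trees, function(tr) {
    og <- tr$tip.label[startsWith(tr$tip.label, "OUT_")]
    smoothed <- nprs_smooth(tr)$tree
    ape::drop.tip(smoothed, og)
  })
  # single-species genera: relabel backbone tips with the species id
  singles <- setdiff(backbone_time$tip.label, names(its_trees))
  single_map <- if (!is.null(genus_map)) {
    sp <- names(genus_map)
    lapply(setNames(singles, singles),
           function(g) sp[genus_map == g][1])
  } else {
    lapply(setNames(singles, singles), identity)
  }
  supertree <- graft(backbone_time, c(species_time, single_map), plans)
  write_newick(supertree, file.path(out_dir, "supertree.nwk"),
               sidecar = TRUE)
  jsonlite::write_json(
    lapply(plans, function(p) p[c("genus", "s_g", "f_g", "a_g", "capped")]),
    file.path(out_dir, "graft_plan.json"), auto_unbox = TRUE, digits = NA)

  ## --- community phylogenetic structure ------------------------------
  # analysis species = matrix species present in the supertree
  in_tree <- colnames(cm$x) %in% supertree$tip.label
  cm_tree <- cm
  cm_tree$x <- cm$x[, in_tree, drop = FALSE]
  nonzero <- rowSums(cm_tree$x) > 0
  cm_tree$x <- cm_tree$x[nonzero, , drop = FALSE]
  cm_tree$samples <- cm_tree$samples[nonzero, , drop = FALSE]
  spec <- null_model_spec(config$null_model, config$n_null_runs)
  cs <- comstruct(cm_tree, supertree, spec, by = "habitat")
  write_tsv(as.data.frame(cs), file.path(out_dir, "comstruct.tsv"))

  ## --- diversity + ordination ----------------------------------------
  habs <- unique(cm$samples$habitat)
  habs <- habs[!is.na(habs)]
  sub_matrix <- function(h) {
    rows <- which(cm$samples$habitat == h)
    x <- cm$x[rows, , drop = FALSE]
    x <- x[, colSums(x) > 0, drop = FALSE]
    community_matrix(x, forest = cm$samples$forest[rows],
                     habitat = cm$samples$habitat[rows])
  }
  per_hab <- lapply(setNames(habs, habs), sub_matrix)
  rf <- do.call(rbind, lapply(habs, function(h) {
    r <- rank_frequency(per_hab[[h]])
    cbind(habitat = h, r,
          singleton_fraction = attr(r, "singleton_fraction"))
  }))
  write_tsv(rf, file.path(out_dir, "rank_frequency.tsv"))
  acc <- do.call(rbind, lapply(habs, function(h)
    cbind(habitat = h, accumulation_curve(per_hab[[h]], n_boot = 1000L))))
  write_tsv(acc, file.path(out_dir, "accumulation.tsv"))
  ov <- if (length(habs) == 2) overlap(per_hab[[1]], per_hab[[2]]) else NULL
  if (!is.null(ov))
    jsonlite::write_json(ov, file.path(out_dir, "overlap.json"),
                         auto_unbox = TRUE, digits = NA)

  occupied <- rowSums(cm$x) > 0
  cm_occ <- cm
  cm_occ$x <- cm$x[occupied, , drop = FALSE]
  cm_occ$samples <- cm$samples[occupied, , drop = FALSE]
  bc <- bray_curtis(cm_occ)
  cf <- connectivity_filter(bc)
  log$n_samples_discarded <- cf$n_discarded +
    sum(!occupied)  # empty samples never enter the graph
  ord <- nmds(bc[cf$kept, cf$kept], k = config$ordination_k)
  log$nmds_stress <- ord$stress
  log$nmds_converged <- ord$converged
  ord_df <- data.frame(sample = rownames(ord$points),
                       habitat = cm_occ$samples$habitat[
                         match(rownames(ord$points), cm_occ$samples$sample)],
                       ord$points, stringsAsFactors = FALSE)
  names(ord_df)[-(1:2)] <- paste0("axis", seq_len(config$ordination_k))
  write_tsv(ord_df, file.path(out_dir, "ordination.tsv"))

  ## --- soils ----------------------------------------------------------
  soils <- compare_soils(soil_raw)
  write_tsv(soils, file.path(out_dir, "soil_anova.tsv"))

  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c("ecmphylo pipeline run",
               paste0(names(log), ": ",
                      vapply(log, function(v) paste(fmt_num(v),
                                                    collapse = ","),
                             character(1)))),
             file.path(out_dir, "log.txt"))
  invisible(list(otus = otus, otu_table = otu_df, matrix = cm,
                 backbone_time = backbone_time, plans = plans,
                 supertree = supertree, comstruct = cs,
                 rank_frequency = rf, accumulation = acc, overlap = ov,
                 ordination = ord, soils = soils, log = log))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `cluster`, `smooth`, `graft`, `comstruct`,
#' `diversity`, `soils`, `all`. Flags mirror [run_config()] /
#' [synthetic_config()] fields (e.g. `--seed 7`,
#' `--similarity-threshold 0.97`, `--n-null-runs 99`, `--synthetic`).
#' Installed as the `exec/ecmphylo` script.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ecmphylo <simulate|cluster|smooth|graft|comstruct|diversity",
    "|soils|all> [--out DIR] [--seed N] [--synthetic] [flags...]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  flags <- args[-1]
  i <- 1
  while (i <= length(flags)) {
    f <- flags[i]
    if (startsWith(f, "--")) {
      key <- gsub("-", "_", sub("^--", "", f))
      if (i < length(flags) && !startsWith(flags[i + 1], "--")) {
        opts[[key]] <- flags[i + 1]; i <- i + 2
      } else {
        opts[[key]] <- TRUE; i <- i + 1
      }
    } else {
      opts$inputs <- c(opts$inputs, f); i <- i + 1
    }
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  out <- opts$out %||% "ecmphylo_out"
  cfg <- run_config(
    similarity_threshold = num(opts$similarity_threshold, 0.95),
    n_null_runs = num(opts$n_null_runs, 999),
    null_model = opts$null_model %||% "independent_swap",
    seed = num(opts$seed, 1),
    crown_cap_beta = num(opts$crown_cap_beta, 0.9),
    ordination_k = num(opts$ordination_k, 2),
    min_hits = num(opts$min_hits, 20))

  status <- tryCatch({
    switch(cmd,
      all = {
        run_pipeline(cfg, out, synthetic = !is.null(opts$synthetic) ||
                       is.null(opts$fasta),
                     inputs = if (is.null(opts$synthetic))
                       opts[c("fasta", "hits", "backbone", "its_trees",
                              "outgroups", "soil")] else NULL)
        0L
      },
      simulate = {
        sc <- synthetic_config(seed = cfg$seed)
        study <- generate_study(sc)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_fasta(study$tip_records, file.path(out, "root_tips_its.fasta"))
        write_newick(study$true_tree, file.path(out, "true_tree.nwk"),
                     sidecar = TRUE)
        write_newick(study$backbone_subs, file.path(out, "backbone_lsu.nwk"),
                     sidecar = TRUE)
        for (h in names(study$matrices))
          write_matrix(study$matrices[[h]],
                       file.path(out, paste0("matrix_", h, ".tsv")))
        write_tsv(study$soil_table, file.path(out, "soil_raw.tsv"))
        jsonlite::write_json(
          list(seed = sc$seed,
               assembly = lapply(study$truth$assembly, function(t)
                 t[c("model", "filter_strength")]),
               genus_map = as.list(study$genus_map)),
          file.path(out, "truth.json"), auto_unbox = TRUE)
        0L
      },
      cluster = {
        if (is.null(opts$fasta)) stop_ecm("cluster needs --fasta FILE")
        rec <- read_fasta(opts$fasta)
        otus <- cluster_otus(rec, cfg$similarity_threshold)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        df <- data.frame(
          otu = vapply(otus, `[[`, character(1), "otu_id"),
          members = vapply(otus, function(o)
            paste(o$member_ids, collapse = ","), character(1)))
        write_tsv(df, file.path(out, "otu_members.tsv"))
        writeLines(paste0(">", df$otu, "\n",
                          vapply(otus, `[[`, character(1), "consensus")),
                   file.path(out, "otu_consensus.fasta"))
        0L
      },
      smooth = {
        if (is.null(opts$tree)) stop_ecm("smooth needs --tree FILE")
        tr <- read_newick(opts$tree, allow_polytomy = TRUE)
        sm <- nprs_smooth(tr)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_newick(sm$tree, file.path(out, "chronogram.nwk"),
                     sidecar = TRUE)
        jsonlite::write_json(list(W = sm$W, rates = sm$rates),
                             file.path(out, "nprs_report.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      comstruct = {
        if (is.null(opts$matrix) || is.null(opts$tree))
          stop_ecm("comstruct needs --matrix FILE --tree FILE")
        m <- read_matrix(opts$matrix)
        tr <- read_newick(opts$tree, allow_polytomy = TRUE)
        spec <- null_model_spec(cfg$null_model, cfg$n_null_runs,
                                seed = cfg$seed)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_tsv(as.data.frame(comstruct(m, tr, spec)),
                  file.path(out, "comstruct.tsv"))
        0L
      },
      diversity = {
        if (is.null(opts$matrix)) stop_ecm("diversity needs --matrix FILE")
        m <- read_matrix(opts$matrix)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_tsv(rank_frequency(m), file.path(out, "rank_frequency.tsv"))
        set.seed(cfg$seed)
        write_tsv(accumulation_curve(m), file.path(out, "accumulation.tsv"))
        occ <- rowSums(m$x) > 0
        m$x <- m$x[occ, , drop = FALSE]
        m$samples <- m$samples[occ, , drop = FALSE]
        bc <- bray_curtis(m)
        cf <- connectivity_filter(bc)
        ordn <- nmds(bc[cf$kept, cf$kept], k = cfg$ordination_k)
        df <- data.frame(sample = rownames(ordn$points), ordn$points)
        write_tsv(df, file.path(out, "ordination.tsv"))
        jsonlite::write_json(list(stress = ordn$stress,
                                  n_discarded = cf$n_discarded),
                             file.path(out, "ordination_stress.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      soils = {
        if (is.null(opts$table)) stop_ecm("soils needs --table FILE")
        tab <- read.delim(opts$table)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_tsv(compare_soils(tab), file.path(out, "soil_anova.tsv"))
        0L
      },
      graft = {
        stop_ecm("graft as a standalone subcommand needs --backbone, ",
                 "--its-trees DIR and --outgroups TSV; run `all` for the ",
                 "integrated pipeline")
      },
      { message(usage); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
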