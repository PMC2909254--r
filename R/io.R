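SEQ_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Read sequence records from FASTA
#'
#' Headers are parsed as `id|marker|sample|forest|habitat`; trailing fields
#' may be omitted and are then unset (`NA`). Residues are normalised to
#' uppercase and must stay within `A,C,G,T,N,-`.
#'
#' @param path FASTA file.
#' @return a data.frame with columns `id`, `marker`, `residues`,
#'   `sample_id`, `forest_id`, `habitat`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_ecm("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_ecm("empty FASTA file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stop_ecm("malformed FASTA at line 1 of ", path, ": expected '>' header")
  idx <- cumsum(is_hdr)
  headers <- sub("^>", "", trimws(lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], idx[!is_hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  # entries with a header but no residue line
  missing <- setdiff(as.character(seq_along(headers)), names(seqs))
  if (length(missing)) {
    ln <- which(is_hdr)[as.integer(missing[1])]
    stop_ecm("malformed FASTA at line ", ln, " of ", path,
             ": header with no sequence")
  }
  seqs <- toupper(seqs[as.character(seq_along(headers))])
  badc <- !vapply(strsplit(seqs, ""),
                  function(s) all(s %in% SEQ_ALPHABET), logical(1))
  if (any(badc)) {
    ln <- which(is_hdr)[which(badc)[1]]
    stop_ecm("invalid residue characters in entry starting at line ", ln,
             " of ", path)
  }
  fields <- strsplit(headers, "|", fixed = TRUE)
  get_f <- function(k) vapply(fields, function(f) {
    v <- if (length(f) >= k) trimws(f[k]) else ""
    if (nzchar(v)) v else NA_character_
  }, character(1))
  rec <- data.frame(
    id = get_f(1), marker = get_f(2), residues = unname(seqs),
    sample_id = get_f(3), forest_id = get_f(4), habitat = get_f(5),
    stringsAsFactors = FALSE
  )
  if (anyNA(rec$id)) stop_ecm("FASTA entry with empty id in ", path)
  if (anyDuplicated(rec$id))
    stop_ecm("duplicate sequence ids in ", path, ": ",
             paste(unique(rec$id[duplicated(rec$id)]), collapse = ", "))
  ok_mark <- is.na(rec$marker) | rec$marker %in% c("ITS", "LSU")
  if (!all(ok_mark))
    stop_ecm("unknown marker in ", path, ": ",
             paste(unique(rec$marker[!ok_mark]), collapse = ", "))
  ok_hab <- is.na(rec$habitat) |
    rec$habitat %in% c("serpentine", "non_serpentine")
  if (!all(ok_hab))
    stop_ecm("unknown habitat label in ", path)
  rec
}

#' Write sequence records to FASTA
#'
#' @param records a data.frame as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    stopifnot(!is.null(names(records)))
    records <- data.frame(id = names(records), residues = unname(records),
                          stringsAsFactors = FALSE)
  }
  hdr_field <- function(x) ifelse(is.na(x), "", x)
  parts <- cbind(records$id,
                 hdr_field(records$marker %||% NA),
                 hdr_field(records$sample_id %||% NA),
                 hdr_field(records$forest_id %||% NA),
                 hdr_field(records$habitat %||% NA))
  hdr <- apply(parts, 1, function(p) {
    p <- p[seq_len(max(1, max(which(nzchar(p)))))]
    paste(p, collapse = "|")
  })
  writeLines(paste0(">", hdr, "\n", records$residues), path)
  invisible(path)
}

#' Sample-by-species presence/absence matrix
#'
#' Container for binary community data with per-sample forest and habitat
#' labels. Cell values must be 0/1, sample and species ids must be unique,
#' and every species must occur in at least one sample.
#'
#' @param x binary matrix, samples in rows (rownames) and species in
#'   columns (colnames).
#' @param forest,habitat optional per-sample label vectors.
#' @return an object of class `community_matrix`: a list with elements
#'   `x` (integer matrix) and `samples` (data.frame of labels).
#' @export
community_matrix <- function(x, forest = NULL, habitat = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_ecm("community matrix needs sample rownames and species colnames")
  rownames(x) <- trimws(rownames(x))
  colnames(x) <- trimws(colnames(x))
  if (anyDuplicated(rownames(x)))
    stop_ecm("duplicate sample ids: ",
             paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x))) stop_ecm("duplicate species ids")
  if (!is_binary01(c(x))) {
    bad <- which(!matrix(x %in% c(0, 1), nrow(x)), arr.ind = TRUE)[1, ]
    stop_ecm("non-binary cell at sample '", rownames(x)[bad[1]],
             "', species '", colnames(x)[bad[2]], "'")
  }
  storage.mode(x) <- "integer"
  if (ncol(x) && any(colSums(x) == 0))
    stop_ecm("species present in no sample: ",
             paste(colnames(x)[colSums(x) == 0], collapse = ", "))
  samples <- data.frame(
    sample = rownames(x),
    forest = if (is.null(forest)) NA_character_ else as.character(forest),
    habitat = if (is.null(habitat)) NA_character_ else as.character(habitat),
    stringsAsFactors = FALSE
  )
  structure(list(x = x, samples = samples), class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix:", nrow(x$x), "samples x", ncol(x$x), "species;",
      sum(x$x), "presences\n")
  if (!all(is.na(x$samples$habitat)))
    cat("habitats:", paste(names(table(x$samples$habitat)), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$x)

#' Read / write a community matrix as TSV
#'
#' Tab-separated; first column `sample`, optional metadata columns
#' `forest` and `habitat`, remaining columns one species each with 0/1
#' cells. `read_matrix(write_matrix(m, p))` is the identity.
#'
#' @param path TSV file.
#' @return a [community_matrix()].
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_ecm("matrix file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"sample" %in% names(df))
    stop_ecm("matrix file must have a 'sample' column: ", path)
  meta <- intersect(c("forest", "habitat"), names(df))
  spp <- setdiff(names(df), c("sample", meta))
  vals <- as.matrix(df[, spp, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(df)))
  if (anyNA(num) || !is_binary01(c(num))) {
    bad <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)[1, ]
    stop_ecm("non-binary cell in ", path, " at sample '",
             df$sample[bad[1]], "', species '", spp[bad[2]], "'")
  }
  rownames(num) <- df$sample
  colnames(num) <- spp
  community_matrix(num,
                  forest = if ("forest" %in% meta) df$forest else NULL,
                  habitat = if ("habitat" %in% meta) df$habitat else NULL)
}

#' @rdname read_matrix
#' @param m a [community_matrix()].
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "community_matrix"))
  df <- data.frame(sample = rownames(m$x), stringsAsFactors = FALSE)
  if (!all(is.na(m$samples$forest))) df$forest <- m$samples$forest
  if (!all(is.na(m$samples$habitat))) df$habitat <- m$samples$habitat
  df <- cbind(df, as.data.frame(m$x, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy hit table
#'
#' TSV with columns `query` and `genus`; rows are rank-ordered hits (best
#' first) within each query, order preserved from the file.
#'
#' @param path TSV file.
#' @return named list mapping each query id to its ordered genus vector.
#' @export
read_taxonomy_hits <- function(path) {
  if (!file.exists(path)) stop_ecm("hit table not found: ", path)
  df <- read.delim(path, colClasses = "character")
  if (!all(c("query", "genus") %in% names(df)))
    stop_ecm("hit table needs 'query' and 'genus' columns: ", path)
  split(df$genus, factor(df$query, levels = unique(df$query)))
}

#' Pipeline run configuration
#'
#' Houses the fixed analysis settings: the 95% sequence-similarity
#' cut-off for OTU delimitation, the 999-run null model, the >= 20
#' unanimous-hit genus-assignment rule, the crown cap used during
#' grafting, and the ordination dimension.
#'
#' @param similarity_threshold OTU similarity cut-off, in (0,1).
#' @param n_null_runs null-model replicates (default 999).
#' @param null_model one of `"independent_swap"`, `"phylogeny_shuffle"`,
#'   `"pool_draw"`.
#' @param seed integer master seed; all stochastic stages draw from the
#'   one stream it initialises.
#' @param crown_cap_beta maximum grafted crown age as a fraction of the
#'   attachment age, in (0,1).
#' @param ordination_k NMDS dimension.
#' @param min_hits hits that must agree for a genus assignment.
#' @return a list of class `run_config`.
#' @export
run_config <- function(similarity_threshold = 0.95,
                       n_null_runs = 999,
                       null_model = c("independent_swap",
                                      "phylogeny_shuffle", "pool_draw"),
                       seed = 1L,
                       crown_cap_beta = 0.9,
                       ordination_k = 2L,
                       min_hits = 20L) {
  null_model <- match.arg(null_model)
  if (!(similarity_threshold > 0 && similarity_threshold < 1))
    stop_ecm("similarity_threshold must be in (0,1)")
  if (n_null_runs < 1) stop_ecm("n_null_runs must be >= 1")
  if (!(crown_cap_beta > 0 && crown_cap_beta < 1))
    stop_ecm("crown_cap_beta must be in (0,1)")
  structure(list(similarity_threshold = similarity_threshold,
                 n_null_runs = as.integer(n_null_runs),
                 null_model = null_model,
                 seed = as.integer(seed),
                 crown_cap_beta = crown_cap_beta,
                 ordination_k = as.integer(ordination_k),
                 min_hits = as.integer(min_hits)),
            class = "run_config")
}
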