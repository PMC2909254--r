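#' Pairwise global-alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, linear
#' gap -2 (compiled in C++ so survey-scale all-pairs clustering stays
#' fast). Identity is the fraction of matching columns among aligned
#' columns, with terminal gap columns excluded from the denominator
#' (reads differ in length, so overhangs carry no information); internal
#' gap columns count as mismatches.
#'
#' @param a,b nucleotide strings (non-empty).
#' @return identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop_ecm("empty sequence")
  nw_align_cpp(toupper(a), toupper(b))$identity
}

# global alignment of `member` against `seed`; returns the two aligned
# strings split into character vectors
align_to_seed <- function(member, seed) {
  al <- nw_align_cpp(member, seed)
  list(member = strsplit(al$a, "")[[1]],
       seed = strsplit(al$b, "")[[1]])
}

#' All-pairs identity matrix
#'
#' @param residues character vector of sequences (names used as ids).
#' @return symmetric matrix of identities, unit diagonal.
#' @export
identity_matrix <- function(residues) {
  n <- length(residues)
  ids <- names(residues) %||% as.character(seq_len(n))
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- pairwise_identity(residues[[i]], residues[[j]])
      }
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Cluster sequences into OTUs at a similarity cut-off
#'
#' Single-linkage agglomeration: two records end in the same OTU iff a
#' chain of pairs with identity `>= threshold` connects them. The
#' partition is order-independent; OTU labels follow first appearance in
#' the input. Identical residue strings are deduplicated before alignment.
#'
#' @param records sequence records (data.frame as from [read_fasta()]);
#'   all must be ITS.
#' @param threshold similarity cut-off (default the conservative 0.95).
#' @return list of OTUs; each has `otu_id`, `member_ids`, `consensus`,
#'   `genus` (`NA` until [assign_genus()]), and `samples` (incidence).
#' @export
cluster_otus <- function(records, threshold = 0.95) {
  if (!nrow(records)) stop_ecm("no sequence records")
  mk <- unique(records$marker[!is.na(records$marker)])
  if (length(mk) > 1)
    stop_ecm("mixed markers in OTU clustering input: ",
             paste(mk, collapse = ", "))
  if (length(mk) == 1 && mk != "ITS")
    stop_ecm("OTU clustering expects ITS sequences, got ", mk)
  uniq <- unique(records$residues)
  uidx <- match(records$residues, uniq)
  nu <- length(uniq)
  # union-find over unique sequences, edges from the identity matrix
  parent <- seq_len(nu)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nu > 1) {
    im <- identity_matrix(uniq)
    for (i in seq_len(nu - 1)) {
      for (j in (i + 1):nu) {
        if (im[i, j] >= threshold && find(i) != find(j)) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  comp <- vapply(seq_len(nu), find, integer(1))
  rec_comp <- comp[uidx]
  otu_order <- unique(rec_comp)  # first-appearance order
  lapply(seq_along(otu_order), function(k) {
    sel <- rec_comp == otu_order[k]
    members <- records$residues[sel]
    list(otu_id = sprintf("OTU%03d", k),
         member_ids = records$id[sel],
         consensus = consensus_sequence(members),
         genus = NA_character_,
         samples = sort(unique(records$sample_id[sel][
           !is.na(records$sample_id[sel])])))
  })
}

# standard IUPAC nucleotide ambiguity codes, keyed by sorted base set
IUPAC_FROM_BASES <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' Majority-rule consensus of an OTU's member sequences
#'
#' Members are pairwise-aligned to the cluster seed (the longest member;
#' first on ties) and projected onto the seed's columns (insertions
#' relative to the seed are dropped). Each column takes the majority base;
#' exact ties take the IUPAC ambiguity code of the tied set; columns where
#' gaps outnumber bases are dropped. `N`s do not vote.
#'
#' @param members character vector of member sequences (non-empty).
#' @return consensus nucleotide string.
#' @export
consensus_sequence <- function(members) {
  if (!length(members)) stop_ecm("empty member list")
  members <- toupper(members)
  if (length(unique(members)) == 1L) return(members[1])
  seed <- members[which.max(nchar(members))]
  L <- nchar(seed)
  rows <- lapply(members, function(m) {
    if (identical(m, seed)) return(strsplit(seed, "")[[1]])
    al <- align_to_seed(m, seed)
    al$member[al$seed != "-"]  # project onto seed columns
  })
  M <- do.call(rbind, rows)
  cons <- vapply(seq_len(L), function(j) {
    col <- M[, j]
    nb <- table(factor(col[col %in% c("A", "C", "G", "T")],
                       levels = c("A", "C", "G", "T")))
    ngap <- sum(col == "-")
    if (ngap > sum(nb)) return("")       # majority gap: drop column
    if (sum(nb) == 0) return("N")
    top <- names(nb)[nb == max(nb)]
    if (length(top) == 1) top else
      IUPAC_FROM_BASES[[paste(sort(top), collapse = "")]]
  }, character(1))
  paste(cons, collapse = "")
}

#' Genus assignment from rank-ordered taxonomy hits
#'
#' A query is confidently assigned iff its first `min_hits` hits exist and
#' all name the same genus; anything else (too few hits, or disagreement
#' within the first `min_hits`) is a rejection, returned as a value with a
#' reason rather than an error.
#'
#' @param hits character vector of genus names, best hit first.
#' @param min_hits unanimity depth (default 20).
#' @return list with `genus` (or `NA`), `rejected`, `reason`.
#' @export
assign_genus <- function(hits, min_hits = 20L) {
  if (length(hits) < min_hits) {
    return(list(genus = NA_character_, rejected = TRUE,
                reason = sprintf("only %d hits, need %d",
                                 length(hits), min_hits)))
  }
  top <- hits[seq_len(min_hits)]
  if (length(unique(top)) == 1L) {
    list(genus = top[1], rejected = FALSE, reason = NA_character_)
  } else {
    list(genus = NA_character_, rejected = TRUE,
         reason = sprintf("first %d hits span %d genera",
                          min_hits, length(unique(top))))
  }
}

#' Community matrix from OTU incidences
#'
#' @param otus list of OTUs from [cluster_otus()].
#' @param sample_meta data.frame with columns `sample_id`, `forest_id`,
#'   `habitat` (e.g. unique rows of the input records); defines the row
#'   set and order.
#' @return a [community_matrix()] (OTUs with no sample incidence dropped).
#' @export
otu_community_matrix <- function(otus, sample_meta) {
  meta <- unique(sample_meta[, c("sample_id", "forest_id", "habitat")])
  if (anyDuplicated(meta$sample_id))
    stop_ecm("conflicting forest/habitat labels for a sample id")
  keep <- otus[vapply(otus, function(o) length(o$samples) > 0, logical(1))]
  x <- vapply(keep, function(o)
    as.integer(meta$sample_id %in% o$samples),
    integer(nrow(meta)))
  if (is.null(dim(x))) x <- matrix(x, nrow = nrow(meta))
  dimnames(x) <- list(meta$sample_id,
                      vapply(keep, `[[`, character(1), "otu_id"))
  community_matrix(x, forest = meta$forest_id, habitat = meta$habitat)
}
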