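#' Gene score table
#'
#' Per-gene fitness scores from a pooled CRISPR knockout screen (negative =
#' sgRNA depletion, i.e. a fitness defect of the knockout).
#'
#' @param gene character vector of unique gene identifiers.
#' @param score finite numeric scores, one per gene.
#' @param label optional screen label.
#' @return an object of class `gene_score_table` (a data.frame).
#' @export
gene_score_table <- function(gene, score, label = NA_character_) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("gene identifiers must be unique")
  if (!is.numeric(score) || anyNA(score) || any(!is.finite(score))) {
    stop("scores must be finite numeric values")
  }
  if (length(gene) != length(score)) stop("'gene' and 'score' lengths differ")
  structure(data.frame(gene = gene, score = score),
            class = c("gene_score_table", "data.frame"), label = label)
}

#' Read / write a gene score TSV (`gene<TAB>score`)
#'
#' @param path file path.
#' @param label optional screen label.
#' @export
read_gene_scores <- function(path, label = NA_character_) {
  df <- utils::read.delim(path, header = TRUE)
  gene_score_table(df[[1L]], df[[2L]], label = label)
}

#' @param tbl a `gene_score_table`.
#' @rdname read_gene_scores
#' @export
write_gene_scores <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Differential screen scores (experimental minus averaged controls)
#'
#' Controls for genotype-independent fitness defects by subtracting the mean
#' of the control-screen scores from the experimental screen, gene by gene.
#' Genes absent from any table are dropped and reported in the `dropped`
#' attribute; differential scoring is only meaningful on shared genes.
#'
#' @param experimental a [gene_score_table] for the knockout screen.
#' @param controls a single control table or list of control tables.
#' @return a [gene_score_table] of differential scores (ordered as the
#'   experimental table), with attribute `dropped` naming excluded genes.
#' @export
differential_scores <- function(experimental, controls) {
  if (inherits(controls, "gene_score_table")) controls <- list(controls)
  if (length(controls) < 1L) stop("need at least one control table")
  tables <- c(list(experimental), controls)
  shared <- Reduce(intersect, lapply(tables, function(t) t$gene))
  if (length(shared) == 0L) stop("empty gene intersection between tables")
  all_genes <- unique(unlist(lapply(tables, function(t) t$gene)))
  dropped <- setdiff(all_genes, shared)
  keep <- experimental$gene[experimental$gene %in% shared]
  ctrl_mat <- vapply(controls, function(t) {
    t$score[match(keep, t$gene)]
  }, numeric(length(keep)))
  ctrl_mean <- rowMeans(matrix(ctrl_mat, nrow = length(keep)))
  diff <- experimental$score[match(keep, experimental$gene)] - ctrl_mean
  out <- gene_score_table(keep, diff,
                          label = paste0(attr(experimental, "label"), "_differential"))
  attr(out, "dropped") <- dropped
  if (length(dropped)) {
    message(length(dropped), " gene(s) absent from at least one table were dropped")
  }
  out
}

#' Hamming distance between equal-length nucleotide sequences
#'
#' Number of mismatched positions between two sequences over the ACGT
#' alphabet; symmetric, and zero iff the sequences are identical.
#'
#' @param a,b character scalars of equal length, alphabet ACGT.
#' @return integer mismatch count.
#' @examples
#' hamming_distance("CGACCTCTACAACTGGGAGG", "CGATCTATACAACTGGGAGG")  # 2
#' @export
hamming_distance <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L) {
    stop("'a' and 'b' must be single character strings")
  }
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  av <- strsplit(toupper(a), "")[[1L]]
  bv <- strsplit(toupper(b), "")[[1L]]
  if (!all(c(av, bv) %in% c("A", "C", "G", "T"))) {
    stop("sequences must use the ACGT alphabet")
  }
  sum(av != bv)
}

#' Scan candidate genomic sites for sgRNA off-targets
#'
#' Returns every candidate site within `max_mismatch` Hamming mismatches of
#' the guide, sorted by mismatch count then input order.  Candidate sites
#' must be supplied (genome-wide enumeration against annotation is out of
#' scope); names of the input vector are carried through as site labels.
#'
#' @param guide guide sequence (e.g. a 20-mer, ACGT).
#' @param candidate_sites character vector of candidate sites, same length
#'   as the guide; may be named.
#' @param max_mismatch maximum number of mismatches for a hit.
#' @return data.frame with columns `site_id, sequence, mismatches` (zero
#'   rows when nothing matches).
#' @export
offtarget_scan <- function(guide, candidate_sites, max_mismatch) {
  if (length(candidate_sites) == 0L) {
    return(data.frame(site_id = character(0), sequence = character(0),
                      mismatches = integer(0)))
  }
  mm <- vapply(candidate_sites, function(s) hamming_distance(guide, s),
               numeric(1), USE.NAMES = FALSE)
  ids <- names(candidate_sites)
  if (is.null(ids)) ids <- paste0("site_", seq_along(candidate_sites))
  hit <- which(mm <= max_mismatch)
  hit <- hit[order(mm[hit], hit)]
  data.frame(site_id = ids[hit], sequence = unname(candidate_sites[hit]),
             mismatches = as.integer(mm[hit]), row.names = NULL)
}
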