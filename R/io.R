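## File formats: TSV interchange tables (all writers emit a header and a
## stable column order, so read(write(x)) round-trips), FASTA alignments via
## Biostrings, newick trees via ape with the post-duplication clade marked
## by a node label.

#' Write / read competition count tables
#'
#' Long-format TSV schema: \code{well_id}, \code{green_genotype},
#' \code{red_genotype}, \code{generation}, \code{red_count},
#' \code{green_count}, \code{total_count}.
#'
#' @param counts data.frame in the schema above (as produced by
#'   \code{\link{simulateScreen}}).
#' @param path file path.
#' @return \code{readCompetitionCounts} returns the data.frame.
#' @export
writeCompetitionCounts <- function(counts, path) {
  cols <- c("well_id", "green_genotype", "red_genotype", "generation",
            "red_count", "green_count", "total_count")
  stopifnot(all(cols %in% names(counts)))
  write.table(counts[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeCompetitionCounts
#' @export
readCompetitionCounts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("well_id", "generation", "red_count", "green_count")
  if (!all(need %in% names(df)))
    stop("count table lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$total_count)) df$total_count <- df$red_count + df$green_count
  bad <- df$total_count != df$red_count + df$green_count
  if (any(bad)) stop("total_count does not equal red + green in ",
                     sum(bad), " row(s)")
  df
}

#' Write / read selection-estimate tables
#'
#' TSV schema: \code{well_id}, \code{green_genotype}, \code{red_genotype},
#' \code{s}, \code{R0_hat}, \code{status}, \code{se}.
#'
#' @param estimates data.frame from \code{\link{fitScreen}}.
#' @param path file path.
#' @export
writeEstimates <- function(estimates, path) {
  cols <- c("well_id", "green_genotype", "red_genotype", "s", "R0_hat",
            "status", "se")
  stopifnot(all(cols %in% names(estimates)))
  write.table(estimates[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeEstimates
#' @export
readEstimates <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Read / write genotype tables
#'
#' Structured text table with one row per occupied locus: columns
#' \code{label}, \code{locus} (\code{BUB1} or \code{MAD3}),
#' \code{provenance}, \code{promoter}, \code{elements} (comma-separated).
#' An absent locus simply has no row.
#'
#' @param path TSV file path.
#' @return \code{readGenotypeTable} returns a named list of
#'   \code{\link{GenotypeSpec}}.
#' @export
readGenotypeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "locus", "provenance", "promoter", "elements")
  if (!all(need %in% names(df)))
    stop("genotype table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- lapply(split(df, factor(df$label, levels = unique(df$label))),
                function(rows) {
    alleles <- setNames(vector("list", 2), c("BUB1", "MAD3"))
    for (i in seq_len(nrow(rows))) {
      el <- strsplit(rows$elements[i], ",")[[1]]
      alleles[[rows$locus[i]]] <- alleleSpec(trimws(el[nzchar(trimws(el))]),
                                             promoter = rows$promoter[i],
                                             provenance = rows$provenance[i])
    }
    genotypeSpec(rows$label[1], bub1 = alleles[["BUB1"]],
                 mad3 = alleles[["MAD3"]])
  })
  out[unique(df$label)]
}

#' @rdname readGenotypeTable
#' @param genotypes named list of \code{GenotypeSpec}.
#' @export
writeGenotypeTable <- function(genotypes, path) {
  rows <- list()
  for (g in genotypes) {
    for (locus in c("BUB1", "MAD3")) {
      a <- if (locus == "BUB1") g@bub1 else g@mad3
      if (is.null(a)) next
      rows[[length(rows) + 1]] <- data.frame(
        label = g@label, locus = locus, provenance = a@provenance,
        promoter = a@promoter,
        elements = paste(a@elements, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write protein alignments as FASTA
#'
#' @param path FASTA file ('-' gaps).
#' @return \code{readAlignmentFasta} returns a character matrix (rows =
#'   sequences).
#' @export
readAlignmentFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(seqs))) != 1)
    stop("sequences are not aligned (unequal lengths)")
  aln <- do.call(rbind, strsplit(as.character(seqs), ""))
  rownames(aln) <- names(seqs)
  aln
}

#' @rdname readAlignmentFasta
#' @param aln character matrix of aligned residues.
#' @export
writeAlignmentFasta <- function(aln, path) {
  seqs <- Biostrings::AAStringSet(apply(aln, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an annotated newick tree
#'
#' Rooted newick with branch lengths; the post-duplication clade is marked
#' by the node label \code{"DUP"} (or any label passed as \code{flag}).
#'
#' @param path newick file.
#' @param flag expected clade label (checked; \code{NA} skips the check).
#' @return An \code{ape::phylo}.
#' @export
readAnnotatedTree <- function(path, flag = "DUP") {
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(tree)) stop("tree is not rooted")
  if (!is.na(flag) && is.na(flaggedNode(tree, flag)))
    stop("tree has no node labelled ", flag)
  tree
}

#' Export a fitness landscape
#'
#' \code{writeLandscapeTable} writes the edge list as TSV (\code{parent},
#' \code{child}, \code{event}, \code{s_rep1}, \code{s_rep2}, \code{call});
#' \code{writeLandscapeDot} writes GraphViz DOT with edges coloured by
#' effect call (red deleterious, green beneficial, black no detectable
#' effect, grey unknown).
#'
#' @param landscape a \code{\link{FitnessLandscape}}.
#' @param path output file.
#' @export
writeLandscapeTable <- function(landscape, path) {
  ed <- landscape@edges
  for (col in c("s_rep1", "s_rep2", "call"))
    if (is.null(ed[[col]])) ed[[col]] <- NA
  write.table(ed[, c("parent", "child", "event", "s_rep1", "s_rep2",
                     "call")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLandscapeTable
#' @export
writeLandscapeDot <- function(landscape, path) {
  ed <- landscape@edges
  col <- if (is.null(ed$call)) rep("gray", nrow(ed)) else
    c(deleterious = "red", beneficial = "green",
      no_detectable_effect = "black", unknown = "gray")[ed$call]
  lines <- c("digraph landscape {",
             paste0("  \"", names(landscape@genotypes), "\";"),
             sprintf("  \"%s\" -> \"%s\" [color=%s, label=\"%s\"];",
                     ed$parent, ed$child, col, ed$event),
             "}")
  writeLines(lines, path)
  invisible(path)
}
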