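# Lipid-metabolism miRNA screen: differentially expressed miRNAs whose
# predicted targets annotate to lipid pathways, then an inverse expression
# concordance filter on the miRNA-target pairs.

#' Default lipid-metabolism pathway terms
#'
#' The four focus pathways: fatty acid biosynthesis, fatty acid elongation,
#' glycerolipid metabolism, and biosynthesis of unsaturated fatty acids.
#' @return Character vector of pathway term names.
#' @export
lipidPathways <- function() {
  c("fatty acid biosynthesis", "fatty acid elongation",
    "glycerolipid metabolism", "biosynthesis of unsaturated fatty acids")
}

#' Screen configuration
#'
#' @param pathways pathway terms of interest (non-empty).
#' @param minLabel minimal DE significance label for a miRNA to enter the
#'   screen (\code{"*"} admits both \code{"*"} and \code{"**"}).
#' @param alpha significance level for a target's expression change in the
#'   concordance rule.
#' @return A list of class \code{ScreenConfig}.
#' @export
screenConfig <- function(pathways = lipidPathways(), minLabel = "*",
                         alpha = 0.05) {
  if (!length(pathways)) stop("pathway set of interest must be non-empty")
  stopifnot(minLabel %in% c("*", "**"))
  structure(list(pathways = pathways, minLabel = minLabel, alpha = alpha),
            class = "ScreenConfig")
}

.de_selected <- function(de, minLabel) {
  if (minLabel == "**") de$label == "**" else de$label %in% c("*", "**")
}

#' Select DE miRNAs with pathway-annotated targets
#'
#' Retains differentially expressed miRNAs that have at least one predicted
#' target gene annotated to at least one pathway of interest, and reports
#' the miRNA-target-pathway edge list.  A target shared by several miRNAs
#' is listed under each.  Screening is monotone in the pathway set:
#' enlarging it never shrinks the shortlist.
#'
#' @param de differential-expression table (from
#'   \code{\link{diffExpression}}): columns name, log2FC, label.
#' @param sites target sites (from \code{\link{scanUTRs}}): columns mirna,
#'   transcript; transcript ids are gene ids.
#' @param annotation data.frame gene/term map (columns gene, term).
#' @param config a \code{\link{screenConfig}}.
#' @return A list: \code{shortlist} (miRNA names), \code{edges}
#'   (data.frame mirna, gene, term).
#' @export
filterByPathway <- function(de, sites, annotation, config = screenConfig()) {
  stopifnot(inherits(config, "ScreenConfig"))
  orphan <- setdiff(unique(sites$mirna), de$name)
  if (length(orphan))
    stop("miRNA id(s) in the site table missing from the DE table: ",
         paste(orphan, collapse = ", "))
  deMir <- de$name[.de_selected(de, config$minLabel)]
  ann <- annotation[annotation$term %in% config$pathways, , drop = FALSE]
  edges <- merge(
    unique(sites[sites$mirna %in% deMir, c("mirna", "transcript")]),
    ann[, c("gene", "term")],
    by.x = "transcript", by.y = "gene")
  if (nrow(edges)) {
    edges <- data.frame(mirna = edges$mirna, gene = edges$transcript,
                        term = edges$term, stringsAsFactors = FALSE)
    edges <- edges[order(edges$mirna, edges$gene, edges$term), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(mirna = character(0), gene = character(0),
                        term = character(0))
  }
  list(shortlist = sort(unique(edges$mirna)), edges = edges)
}

#' Inverse expression concordance screen
#'
#' For each shortlisted miRNA, flags each of its pathway-annotated targets
#' as concordant when the target's expression change is significant and of
#' opposite sign to the miRNA's (the operational reading of a significant
#' inverse correlation when each condition has one sample).  A miRNA's
#' verdict is retained iff at least one target is concordant; targets with
#' missing expression are flagged "untested" and not counted.
#'
#' @param shortlist result of \code{\link{filterByPathway}} (or a list with
#'   \code{edges}).
#' @param de differential-expression table with columns name, log2FC.
#' @param targetExpr data.frame of gene-level expression changes: columns
#'   gene, log2FC, pvalue.
#' @param config a \code{\link{screenConfig}}.
#' @return A list: \code{verdicts} (data.frame mirna, direction, nTargets,
#'   nConcordant, retained), \code{detail} (per miRNA-target pair: mirna,
#'   gene, terms, mirLog2FC, targetLog2FC, targetP, status in
#'   concordant/discordant/untested).
#' @export
inverseCorrelationScreen <- function(shortlist, de, targetExpr,
                                     config = screenConfig()) {
  stopifnot(inherits(config, "ScreenConfig"))
  edges <- shortlist$edges
  pairs <- unique(edges[, c("mirna", "gene")])
  detail <- NULL
  if (nrow(pairs)) {
    mirFC <- de$log2FC[match(pairs$mirna, de$name)]
    idx <- match(pairs$gene, targetExpr$gene)
    tFC <- targetExpr$log2FC[idx]
    tP <- targetExpr$pvalue[idx]
    status <- ifelse(is.na(idx), "untested",
      ifelse(tP < config$alpha & sign(tFC) * sign(mirFC) < 0,
             "concordant", "discordant"))
    terms <- vapply(seq_len(nrow(pairs)), function(i) {
      paste(sort(unique(edges$term[edges$mirna == pairs$mirna[i] &
                                   edges$gene == pairs$gene[i]])),
            collapse = ";")
    }, character(1))
    detail <- data.frame(mirna = pairs$mirna, gene = pairs$gene,
                         terms = terms, mirLog2FC = mirFC,
                         targetLog2FC = tFC, targetP = tP, status = status,
                         stringsAsFactors = FALSE)
  } else {
    detail <- data.frame(mirna = character(0), gene = character(0),
                         terms = character(0), mirLog2FC = numeric(0),
                         targetLog2FC = numeric(0), targetP = numeric(0),
                         status = character(0))
  }
  mirs <- sort(unique(detail$mirna))
  verdicts <- data.frame(
    mirna = mirs,
    direction = ifelse(de$log2FC[match(mirs, de$name)] > 0, "up", "down"),
    nTargets = vapply(mirs, function(m) sum(detail$mirna == m), integer(1)),
    nConcordant = vapply(mirs, function(m)
      sum(detail$mirna == m & detail$status == "concordant"), integer(1)),
    stringsAsFactors = FALSE)
  verdicts$retained <- verdicts$nConcordant >= 1
  rownames(verdicts) <- NULL
  list(verdicts = verdicts, detail = detail)
}
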