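# Drug-network meta-analysis: phenotype presence matrices, disease-gene
# overlaps, one-hot encodings, hierarchical clustering, per-group gene
# ranking by ridge logistic regression, and group association fractions.

#' Drug network set
#'
#' Bundle of the four meta-analysis inputs: per-drug network gene sets,
#' gene-to-phenotype annotations, a phenotype-to-cluster partition and
#' per-drug effect-group labels. Empty gene sets are legal (drugs whose
#' network retains no annotated gene appear as white rows in heatmaps).
#'
#' @param drug_genes Named list: drug id -> character vector of gene ids.
#' @param gene_phenotypes data.frame with columns gene_id, phenotype_id.
#' @param phenotype_clusters Named character vector: phenotype id -> cluster.
#' @param drug_groups Named character vector: drug id -> effect group.
#' @return An object of class `drug_network_set`.
#' @export
drug_network_set <- function(drug_genes, gene_phenotypes,
                             phenotype_clusters, drug_groups) {
  stopifnot(is.list(drug_genes), !is.null(names(drug_genes)))
  if (!all(c("gene_id", "phenotype_id") %in% names(gene_phenotypes))) {
    stop("gene_phenotypes needs columns gene_id, phenotype_id")
  }
  missing <- setdiff(names(drug_groups), names(drug_genes))
  if (length(missing)) {
    stop("drugs in drug_groups without a network entry: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(names(phenotype_clusters))) {
    stop("phenotype_clusters maps a phenotype more than once")
  }
  structure(list(drug_genes = drug_genes,
                 gene_phenotypes = gene_phenotypes,
                 phenotype_clusters = phenotype_clusters,
                 drug_groups = drug_groups),
            class = "drug_network_set")
}

#' Read a drug network set from TSV tables
#'
#' @param drug_genes_path TSV with columns drug_id, gene_id.
#' @param gene_phenotypes_path TSV with columns gene_id, phenotype_id.
#' @param phenotype_clusters_path TSV with columns phenotype_id, cluster_id.
#' @param drug_groups_path TSV with columns drug_id, group.
#' @return A [drug_network_set()].
#' @export
read_network_tables <- function(drug_genes_path, gene_phenotypes_path,
                                phenotype_clusters_path, drug_groups_path) {
  tsv <- function(p) utils::read.delim(p, colClasses = "character")
  dg <- tsv(drug_genes_path)
  gp <- tsv(gene_phenotypes_path)
  pc <- tsv(phenotype_clusters_path)
  gr <- tsv(drug_groups_path)
  groups <- stats::setNames(gr$group, gr$drug_id)
  genes <- split(dg$gene_id, dg$drug_id)
  # drugs labeled but with no network rows keep an empty set
  empty <- setdiff(names(groups), names(genes))
  genes[empty] <- list(character(0))
  drug_network_set(genes, gp,
                   stats::setNames(pc$cluster_id, pc$phenotype_id), groups)
}

#' Drug x phenotype presence matrix
#'
#' Entry (d, p) is 1 when drug d's network genes intersect the gene set
#' annotated to phenotype p.
#'
#' @param nets A [drug_network_set()].
#' @param phenotype_ids Phenotypes to include (default: all annotated, plus
#'   all clustered phenotypes).
#' @return Binary matrix, drugs x phenotypes.
#' @export
phenotype_presence_matrix <- function(nets, phenotype_ids = NULL) {
  ann <- split(nets$gene_phenotypes$gene_id, nets$gene_phenotypes$phenotype_id)
  if (is.null(phenotype_ids)) {
    phenotype_ids <- sort(unique(c(names(ann), names(nets$phenotype_clusters))))
  } else {
    known <- unique(c(names(ann), names(nets$phenotype_clusters)))
    bad <- setdiff(phenotype_ids, known)
    if (length(bad)) stop("unknown phenotype id(s): ", paste(bad, collapse = ", "))
  }
  drugs <- names(nets$drug_genes)
  m <- matrix(0L, nrow = length(drugs), ncol = length(phenotype_ids),
              dimnames = list(drugs, phenotype_ids))
  for (p in phenotype_ids) {
    pg <- ann[[p]]
    if (is.null(pg) || length(pg) == 0) next
    m[, p] <- vapply(nets$drug_genes,
                     function(g) as.integer(any(g %in% pg)), integer(1))
  }
  m
}

#' Intersect each drug network with a disease-gene universe
#'
#' @param nets A [drug_network_set()].
#' @param disease_gene_universe Character vector of disease-associated genes.
#' @return Named list: drug id -> overlapping gene ids (possibly empty).
#' @export
disease_gene_overlap <- function(nets, disease_gene_universe) {
  if (length(disease_gene_universe) == 0) stop("gene universe is empty")
  lapply(nets$drug_genes, function(g) sort(intersect(g, disease_gene_universe)))
}

#' One-hot drug x gene matrix from overlap sets
#'
#' @param overlaps Named list: drug id -> gene ids.
#' @param gene_order Column order; default the sorted union of all genes.
#' @return Binary matrix, drugs x genes.
#' @export
one_hot_matrix <- function(overlaps, gene_order = NULL) {
  if (is.null(gene_order)) gene_order <- sort(unique(unlist(overlaps)))
  if (anyDuplicated(gene_order)) stop("duplicate gene in gene_order")
  extra <- setdiff(unique(unlist(overlaps)), gene_order)
  if (length(extra)) stop("gene_order does not cover: ", paste(extra, collapse = ", "))
  m <- matrix(0L, nrow = length(overlaps), ncol = length(gene_order),
              dimnames = list(names(overlaps), gene_order))
  for (i in seq_along(overlaps)) m[i, overlaps[[i]]] <- 1L
  m
}

#' Hierarchically cluster drugs on a binary matrix
#'
#' Default distance is Jaccard (fraction of discordant features among
#' features present in either drug) with average linkage; identical rows
#' merge at height 0 and sit on adjacent leaves. Pairs of all-zero rows have
#' an undefined Jaccard distance and are assigned distance 0 (with a
#' warning), so empty networks co-cluster.
#'
#' @param m Binary matrix, drugs x features (>= 2 rows).
#' @param distance `"jaccard"` or `"euclidean"`.
#' @param linkage `"average"` or `"ward.D2"`.
#' @return List with `hclust` (the merge tree) and `leaf_order` (row ids in
#'   dendrogram order).
#' @export
cluster_drugs <- function(m, distance = c("jaccard", "euclidean"),
                          linkage = c("average", "ward.D2")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (nrow(m) < 2) stop("need at least 2 rows to cluster")
  if (distance == "jaccard" && any(rowSums(m != 0) == 0)) {
    warning("all-zero rows present; pairs of empty rows get distance 0")
  }
  d <- if (distance == "jaccard") stats::dist(m, method = "binary")
       else stats::dist(m, method = "euclidean")
  if (anyNA(d)) d[is.na(d)] <- 0
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, leaf_order = rownames(m)[hc$order])
}

# Ridge (L2) logistic regression via glmnet at a single fixed lambda.
# `c_strength` follows the inverse-regularization convention: the penalized
# objective is -loglik/n + ||beta||^2 / (2 * n * c_strength).
ridge_logistic <- function(x, y, c_strength = 1) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  n <- nrow(x)
  xx <- if (ncol(x) == 1) cbind(x, .pad = 0) else x  # glmnet needs >= 2 cols
  fit <- glmnet::glmnet(xx, y, family = "binomial", alpha = 0,
                        lambda = 1 / (n * c_strength),
                        standardize = FALSE, thresh = 1e-12)
  beta <- as.numeric(fit$beta)[seq_len(ncol(x))]
  names(beta) <- colnames(x)
  list(intercept = as.numeric(fit$a0), beta = beta, fit = fit,
       config = list(penalty = "l2", c_strength = c_strength,
                     lambda = 1 / (n * c_strength), solver = "glmnet",
                     standardize = FALSE))
}

#' Rank genes per effect group by one-vs-rest ridge logistic regression
#'
#' For each effect group, fits an L2-regularized logistic regression of
#' group membership on the binary gene columns (one-vs-rest; intercept
#' unpenalized; deterministic solver) and ranks genes by descending
#' coefficient, breaking ties lexicographically by gene id. Groups with
#' fewer than two members are skipped with a warning. Regularization keeps
#' perfectly separating columns finite.
#'
#' @param m Binary drug x gene matrix with row and column names.
#' @param groups Named character vector: drug id -> group (names must cover
#'   the rows of `m`).
#' @param c_strength Inverse regularization strength (default 1).
#' @return data.frame with columns group, gene, coefficient, rank; the
#'   regression configuration is attached as attribute `"config"`.
#' @export
group_gene_regression <- function(m, groups, c_strength = 1) {
  if (ncol(m) < 1) stop("need at least one gene column")
  g <- groups[rownames(m)]
  if (anyNA(g)) stop("groups must label every row of m")
  lv <- sort(unique(g))
  if (length(lv) < 2) stop("need at least two groups")
  out <- list(); cfg <- NULL
  for (grp in lv) {
    y <- as.integer(g == grp)
    if (sum(y) < 2 || sum(1 - y) < 2) {
      warning("skipping group '", grp,
              "' with fewer than 2 members in group or rest")
      next
    }
    rl <- ridge_logistic(m, y, c_strength)
    cfg <- rl$config
    ord <- order(-rl$beta, colnames(m))
    out[[grp]] <- data.frame(group = grp, gene = colnames(m)[ord],
                             coefficient = unname(rl$beta[ord]),
                             rank = seq_along(ord), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "config") <- cfg
  res
}

#' Per-group phenotype association fractions
#'
#' For each effect group, the number of drugs with at least one phenotype
#' presence (overall and per phenotype cluster) over the group size --- the
#' "k/n drugs had at least one network association" summary.
#'
#' @param groups Named character vector: drug id -> group.
#' @param presence Binary drug x phenotype matrix from
#'   [phenotype_presence_matrix()].
#' @param clusters Optional named vector phenotype id -> cluster; when given,
#'   per-cluster rows are added.
#' @return data.frame with columns group, cluster ("all" for the overall
#'   row), n_with_association, group_size, fraction.
#' @export
group_phenotype_fractions <- function(groups, presence, clusters = NULL) {
  missing <- setdiff(names(groups), rownames(presence))
  if (length(missing)) {
    stop("drugs without presence rows: ", paste(missing, collapse = ", "))
  }
  scopes <- list(all = colnames(presence))
  if (!is.null(clusters)) {
    for (cl in sort(unique(clusters))) {
      scopes[[cl]] <- intersect(names(clusters)[clusters == cl],
                                colnames(presence))
    }
  }
  out <- list()
  for (grp in sort(unique(groups))) {
    drugs <- names(groups)[groups == grp]
    sub <- presence[drugs, , drop = FALSE]
    for (sc in names(scopes)) {
      cols <- scopes[[sc]]
      hit <- if (length(cols)) sum(rowSums(sub[, cols, drop = FALSE]) > 0) else 0L
      out[[length(out) + 1L]] <- data.frame(
        group = grp, cluster = sc, n_with_association = hit,
        group_size = length(drugs), fraction = hit / length(drugs),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
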