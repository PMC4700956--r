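# The bipartite miRNA -> gene targeting network with ortholog/paralog
# homology edges, and the redundancy statistics computed on it: unique vs
# shared targets per miRNA, homolog-pair sharing fractions, family-size /
# miRNA-count correlation, and targeted fractions per species.

#' Build a targeting network
#'
#' One directed targeting edge per (miRNA, gene) best site; undirected
#' homology edges are derived from family and species labels: paralog =
#' same family and same species, ortholog = same family and different
#' species.  Genes with no predicted site are kept as isolated nodes so
#' denominators are correct.
#'
#' @param sites data.frame of best sites (`mirna_id`, `gene_id`,
#'   `expectation`) or a [predict_targets()] result (its `best` table is
#'   used).
#' @param family_map data.frame with `gene_id`, `species`, `family_id`
#'   covering every gene (including never-targeted ones).
#' @return object of class `"targeting_network"`.
#' @export
build_network <- function(sites, family_map) {
  if (inherits(sites, "target_prediction")) sites <- sites$best
  need <- c("gene_id", "species", "family_id")
  if (!all(need %in% names(family_map)))
    stop("family_map needs columns gene_id, species, family_id",
         call. = FALSE)
  missing <- setdiff(unique(sites$gene_id), family_map$gene_id)
  if (length(missing))
    stop("genes missing from family_map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  genes <- unique(family_map[, need])
  if (anyDuplicated(genes$gene_id))
    stop("conflicting family/species assignments for some genes",
         call. = FALSE)
  targeting <- unique(sites[, intersect(c("mirna_id", "gene_id",
                                          "expectation"), names(sites))])
  hom <- list()
  for (f in unique(genes$family_id)) {
    g <- genes[genes$family_id == f, , drop = FALSE]
    if (nrow(g) < 2) next
    prs <- combn(seq_len(nrow(g)), 2)
    hom[[length(hom) + 1]] <- data.frame(
      gene_a = g$gene_id[prs[1, ]], gene_b = g$gene_id[prs[2, ]],
      family_id = f,
      relation = ifelse(g$species[prs[1, ]] == g$species[prs[2, ]],
                        "paralog", "ortholog"),
      stringsAsFactors = FALSE)
  }
  homology <- if (length(hom)) do.call(rbind, hom) else
    data.frame(gene_a = character(0), gene_b = character(0),
               family_id = character(0), relation = character(0))
  structure(list(mirnas = sort(unique(targeting$mirna_id)),
                 genes = genes, targeting = targeting,
                 homology = homology),
            class = "targeting_network")
}

#' @export
print.targeting_network <- function(x, ...) {
  cat(sprintf(
    "<targeting_network> %d miRNAs, %d genes, %d targeting edges, %d homology edges\n",
    length(x$mirnas), nrow(x$genes), nrow(x$targeting), nrow(x$homology)))
  invisible(x)
}

# incoming miRNA id set per gene
incoming_sets <- function(net) {
  s <- split(net$targeting$mirna_id, net$targeting$gene_id)
  out <- setNames(vector("list", nrow(net$genes)), net$genes$gene_id)
  out[names(s)] <- lapply(s, unique)
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' Unique and shared target counts per miRNA
#'
#' A target gene is unique to miRNA `m` iff `m` is its only incoming
#' miRNA (within the gene's species set); otherwise it is shared.  The
#' two counts partition each miRNA's targets.
#'
#' @param net a [build_network()] result.
#' @return data.frame (`mirna_id`, `n_unique`, `n_shared`).
#' @export
unique_shared_counts <- function(net) {
  inc <- incoming_sets(net)
  indeg <- vapply(inc, length, integer(1))
  do.call(rbind, lapply(net$mirnas, function(m) {
    targ <- unique(net$targeting$gene_id[net$targeting$mirna_id == m])
    data.frame(mirna_id = m,
               n_unique = sum(indeg[targ] == 1L),
               n_shared = sum(indeg[targ] >= 2L),
               stringsAsFactors = FALSE)
  }))
}

#' Sharing statistics over homologous gene pairs
#'
#' For every unordered within-family gene pair of the requested relation,
#' compares the incoming miRNA sets: `frac_share_any` is the fraction of
#' pairs whose sets intersect, `frac_identical` the fraction with equal
#' sets.  Pairs in which both genes have empty sets are excluded and
#' counted.  With `unit = "gene"` the fractions are computed per gene
#' instead: a gene shares (or matches) if any of its homologs of that
#' relation does.
#'
#' @param net a [build_network()] result.
#' @param relation `"ortholog"` or `"paralog"`.
#' @param unit `"pair"` (default) or `"gene"`.
#' @param canonical optional function mapping miRNA ids to a canonical
#'   name before cross-species comparison (default identity).
#' @return object of class `"sharing_summary"`: list with `relation`,
#'   `n_pairs`, `n_excluded`, `frac_share_any`, `frac_identical` and,
#'   for paralogs, `per_species` breakdown.
#' @export
homolog_sharing <- function(net, relation = c("ortholog", "paralog"),
                            unit = c("pair", "gene"), canonical = identity) {
  relation <- match.arg(relation)
  unit <- match.arg(unit)
  prs <- net$homology[net$homology$relation == relation, , drop = FALSE]
  inc <- lapply(incoming_sets(net), function(s) unique(canonical(s)))
  if (nrow(prs) == 0) {
    return(structure(list(relation = relation, unit = unit, n_pairs = 0L,
                          n_excluded = 0L, frac_share_any = NA_real_,
                          frac_identical = NA_real_, per_species = NULL),
                     class = "sharing_summary"))
  }
  a <- inc[prs$gene_a]
  b <- inc[prs$gene_b]
  both_empty <- vapply(seq_len(nrow(prs)), function(i)
    length(a[[i]]) == 0 && length(b[[i]]) == 0, logical(1))
  share <- vapply(seq_len(nrow(prs)), function(i)
    length(intersect(a[[i]], b[[i]])) > 0, logical(1))
  ident <- vapply(seq_len(nrow(prs)), function(i)
    setequal(a[[i]], b[[i]]) && length(a[[i]]) > 0, logical(1))
  inc_rows <- !both_empty
  per_species <- NULL
  if (unit == "pair") {
    n_pairs <- sum(inc_rows)
    fs <- if (n_pairs) mean(share[inc_rows]) else NA_real_
    fi <- if (n_pairs) mean(ident[inc_rows]) else NA_real_
    if (relation == "paralog" && n_pairs) {
      spec <- net$genes$species[match(prs$gene_a, net$genes$gene_id)]
      per_species <- do.call(rbind, lapply(unique(spec), function(sp) {
        sel <- inc_rows & spec == sp
        data.frame(species = sp, n_pairs = sum(sel),
                   frac_share_any = if (any(sel)) mean(share[sel]) else NA,
                   frac_identical = if (any(sel)) mean(ident[sel]) else NA,
                   stringsAsFactors = FALSE)
      }))
    }
  } else {
    # gene unit: a gene shares if any homolog pair it belongs to shares
    gs <- unique(c(prs$gene_a, prs$gene_b))
    gene_stat <- function(stat) vapply(gs, function(g) {
      sel <- inc_rows & (prs$gene_a == g | prs$gene_b == g)
      if (!any(sel)) NA else any(stat[sel])
    }, logical(1))
    has_pair <- vapply(gs, function(g)
      any(inc_rows & (prs$gene_a == g | prs$gene_b == g)), logical(1))
    n_pairs <- sum(has_pair)
    fs <- if (n_pairs) mean(gene_stat(share)[has_pair]) else NA_real_
    fi <- if (n_pairs) mean(gene_stat(ident)[has_pair]) else NA_real_
  }
  out <- structure(list(relation = relation, unit = unit,
                        n_pairs = as.integer(n_pairs),
                        n_excluded = as.integer(sum(both_empty)),
                        frac_share_any = fs, frac_identical = fi,
                        per_species = per_species),
                   class = "sharing_summary")
  if (!is.na(fs) && !is.na(fi) && fi > fs + 1e-12)
    stop("internal error: frac_identical > frac_share_any", call. = FALSE)
  out
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary %s/%s> n=%d (excluded %d) share_any=%s identical=%s\n",
              x$relation, x$unit, x$n_pairs, x$n_excluded,
              format(x$frac_share_any), format(x$frac_identical)))
  invisible(x)
}

#' Correlation of R-gene family size with miRNA count
#'
#' Spearman rank correlation (ties mid-ranked) between the number of
#' genes per family and the number of distinct miRNAs with at least one
#' edge into the family.  The p-value is computed by exact permutation
#' for n <= 10 families and by the t-approximation otherwise.
#'
#' @param net a [build_network()] result.
#' @param per_species if TRUE, families are counted per species (each
#'   species' gene set of a family is a separate observation).
#' @return list with `rho`, `p_value`, `n` and the underlying table.
#' @export
family_size_vs_mirna_count <- function(net, per_species = FALSE) {
  g <- net$genes
  key <- if (per_species) paste(g$family_id, g$species) else g$family_id
  fams <- unique(key)
  if (length(fams) < 3) stop("need >= 3 families", call. = FALSE)
  size <- vapply(fams, function(f) sum(key == f), integer(1))
  n_mirna <- vapply(fams, function(f) {
    genes_f <- g$gene_id[key == f]
    length(unique(net$targeting$mirna_id[net$targeting$gene_id %in% genes_f]))
  }, integer(1))
  if (length(unique(size)) == 1 || length(unique(n_mirna)) == 1) {
    warning("constant vector; correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(fams),
                table = data.frame(family = fams, size = size,
                                   n_mirna = n_mirna)))
  }
  rho <- cor(size, n_mirna, method = "spearman")
  n <- length(fams)
  p <- if (n <= 10) {
    .spearman_perm_p_cpp(rank(size), rank(n_mirna))
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p_value = p, n = n,
       table = data.frame(family = fams, size = size, n_mirna = n_mirna,
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Fraction of a species' genes with a predicted site
#'
#' @param net a [build_network()] result (isolated genes must be present
#'   for the denominator to be correct).
#' @param species species label.
#' @param max_expectation optional cutoff applied to the targeting edges
#'   (default: all edges in the network).
#' @return list (`n_targeted`, `n_total`, `fraction`).
#' @export
targeted_fraction <- function(net, species, max_expectation = Inf) {
  genes_sp <- net$genes$gene_id[net$genes$species == species]
  if (length(genes_sp) == 0)
    stop("no genes for species ", species, call. = FALSE)
  t <- net$targeting
  if (is.finite(max_expectation) && "expectation" %in% names(t))
    t <- t[t$expectation <= max_expectation, , drop = FALSE]
  n_t <- sum(genes_sp %in% t$gene_id)
  list(n_targeted = n_t, n_total = length(genes_sp),
       fraction = n_t / length(genes_sp))
}

#' Convert a targeting network to igraph
#' @param net a [build_network()] result.
#' @return an igraph graph: miRNA and gene vertices, directed targeting
#'   edges and undirected homology edges (attribute `relation`).
#' @export
as_igraph <- function(net) {
  verts <- rbind(
    data.frame(name = net$mirnas, type = "mirna", species = NA,
               family_id = NA, stringsAsFactors = FALSE),
    data.frame(name = net$genes$gene_id, type = "gene",
               species = net$genes$species,
               family_id = net$genes$family_id, stringsAsFactors = FALSE))
  edges <- rbind(
    data.frame(from = net$targeting$mirna_id, to = net$targeting$gene_id,
               relation = "targeting",
               expectation = net$targeting$expectation,
               stringsAsFactors = FALSE),
    data.frame(from = net$homology$gene_a, to = net$homology$gene_b,
               relation = net$homology$relation, expectation = NA,
               stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Export a targeting network
#'
#' Formats: `"tsv"` (native, lossless: node and edge rows in one table;
#' round-trips byte-identically through [import_network()]), `"graphml"`
#' (via igraph) and `"sif"` (one line per edge).
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @param format `"tsv"`, `"graphml"` or `"sif"`.
#' @return invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    rows <- rbind(
      data.frame(record = "mirna", id = net$mirnas, to = "", species = "",
                 family_id = "", relation = "", expectation = "",
                 stringsAsFactors = FALSE),
      data.frame(record = "gene", id = net$genes$gene_id, to = "",
                 species = net$genes$species,
                 family_id = net$genes$family_id, relation = "",
                 expectation = "", stringsAsFactors = FALSE),
      data.frame(record = "targeting", id = net$targeting$mirna_id,
                 to = net$targeting$gene_id, species = "", family_id = "",
                 relation = "targeting",
                 expectation = format(net$targeting$expectation,
                                      digits = 15, trim = TRUE),
                 stringsAsFactors = FALSE),
      data.frame(record = "homology", id = net$homology$gene_a,
                 to = net$homology$gene_b, species = "",
                 family_id = net$homology$family_id,
                 relation = net$homology$relation, expectation = "",
                 stringsAsFactors = FALSE))
    write_tsv(rows, path)
  } else if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- c(
      sprintf("%s\ttargets\t%s", net$targeting$mirna_id,
              net$targeting$gene_id),
      sprintf("%s\t%s\t%s", net$homology$gene_a, net$homology$relation,
              net$homology$gene_b))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Import a network exported in the native TSV format
#' @param path file written by `export_network(..., format = "tsv")`.
#' @return a `"targeting_network"` object.
#' @export
import_network <- function(path) {
  rows <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = "character", na.strings = NULL)
  genes <- rows[rows$record == "gene", ]
  targ <- rows[rows$record == "targeting", ]
  hom <- rows[rows$record == "homology", ]
  structure(list(
    mirnas = rows$id[rows$record == "mirna"],
    genes = data.frame(gene_id = genes$id, species = genes$species,
                       family_id = genes$family_id,
                       stringsAsFactors = FALSE),
    targeting = data.frame(mirna_id = targ$id, gene_id = targ$to,
                           expectation = as.numeric(targ$expectation),
                           stringsAsFactors = FALSE),
    homology = data.frame(gene_a = hom$id, gene_b = hom$to,
                          family_id = hom$family_id,
                          relation = hom$relation,
                          stringsAsFactors = FALSE)),
    class = "targeting_network")
}

#' Greedy single-linkage family clustering from homology pairs
#'
#' Fallback family assignment for fixtures when no curated family map is
#' available: connected components of the homology-pair graph after an
#' e-value filter.
#'
#' @param pairs data.frame (`gene_a`, `gene_b`, `evalue`).
#' @param genes character vector of all gene ids (singletons become their
#'   own family).
#' @param max_evalue e-value cutoff (default 1e-4).
#' @return data.frame (`gene_id`, `family_id`).
#' @export
cluster_families <- function(pairs, genes, max_evalue = 1e-4) {
  keep <- pairs[pairs$evalue < max_evalue, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    keep[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes))
  comp <- igraph::components(g)$membership
  data.frame(gene_id = names(comp),
             family_id = sprintf("fam%d", unname(comp)),
             stringsAsFactors = FALSE, row.names = NULL)
}
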