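# Bipartite network construction, degree-class abundances, hubs, overlaps.

#' Build the bipartite miRNA-mRNA network
#'
#' @param edges Deduplicated edge tibble (or any tibble with `mirna_id` and
#'   `gene_id` columns); a duplicated pair is an error — run
#'   [deduplicate()] first.
#' @return An object of class `"mirna_network"`: a list with the edge
#'   tibble and per-side degree tibbles (`mirna_degree`, `gene_degree`,
#'   each with columns `id`, `degree`).
#' @export
build_network <- function(edges) {
  stopifnot(all(c("mirna_id", "gene_id") %in% names(edges)))
  key <- paste(edges$mirna_id, edges$gene_id, sep = "\t")
  if (anyDuplicated(key) > 0) {
    abort("duplicate (mirna_id, gene_id) pair in input; deduplicate() first")
  }
  e <- tibble(mirna_id = edges$mirna_id, gene_id = edges$gene_id) |>
    arrange(.data$mirna_id, .data$gene_id)
  deg <- function(ids) {
    count(tibble(id = ids), .data$id, name = "degree") |> arrange(.data$id)
  }
  structure(
    list(edges = e, mirna_degree = deg(e$mirna_id), gene_degree = deg(e$gene_id)),
    class = "mirna_network"
  )
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("<mirna_network> %d edges, %d miRNAs, %d genes\n",
              nrow(x$edges), nrow(x$mirna_degree), nrow(x$gene_degree)))
  invisible(x)
}

.network_side <- function(network, side = c("gene", "mirna")) {
  side <- match.arg(side)
  if (side == "gene") network$gene_degree else network$mirna_degree
}

#' Degree-class abundance table
#'
#' For one side of the bipartite network, counts how many nodes share each
#' exact degree value — the abundance of that degree class. E.g. if two
#' genes each interact with 94 miRNAs, degree 94 has abundance 2. Degrees
#' with no nodes are omitted; rows are sorted by increasing degree.
#'
#' @param network A [build_network()] object.
#' @param side `"gene"` or `"mirna"`.
#' @return Tibble of class `"degree_abundance"` with columns `degree`,
#'   `abundance`, and the side stored as the `"side"` attribute.
#' @export
degree_abundance <- function(network, side = c("gene", "mirna")) {
  side <- match.arg(side)
  deg <- .network_side(network, side)
  out <- count(deg, degree = .data$degree, name = "abundance") |>
    arrange(.data$degree)
  attr(out, "side") <- side
  class(out) <- c("degree_abundance", class(out))
  out
}

#' Network hubs
#'
#' Nodes with degree strictly greater than the threshold. Genes regulated
#' by more than 20 distinct miRNAs are the conventional hub definition for
#' this network.
#'
#' @param network A [build_network()] object.
#' @param side `"gene"` (default) or `"mirna"`.
#' @param threshold Non-negative integer; strict lower bound on degree.
#' @return Tibble with columns `id`, `degree`, sorted by decreasing degree
#'   then id.
#' @export
find_hubs <- function(network, side = c("gene", "mirna"), threshold = 20) {
  side <- match.arg(side)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("threshold must be a single non-negative number")
  }
  .network_side(network, side) |>
    filter(.data$degree > threshold) |>
    arrange(dplyr::desc(.data$degree), .data$id)
}

.targets_of <- function(network, mirna_id) {
  network$edges$gene_id[network$edges$mirna_id == mirna_id]
}

#' Target-set overlaps between miRNAs
#'
#' Venn-style comparison of the target gene sets of selected miRNAs.
#' In `pairwise` mode every pair is compared (set sizes, intersection size
#' and sorted members); in `full` mode genes are assigned to exact Venn
#' regions (the subset of query miRNAs targeting them) and counted.
#'
#' @param network A [build_network()] object.
#' @param mirna_ids Character vector of at least two miRNA ids present in
#'   the network (an unknown id is an error naming it).
#' @param mode `"pairwise"` or `"full"`.
#' @return In pairwise mode a tibble `a`, `b`, `size_a`, `size_b`,
#'   `n_common`, `common` (list-column); in full mode a tibble `region`
#'   (ampersand-joined miRNA ids), `n`, `members` (list-column).
#' @export
target_overlap <- function(network, mirna_ids, mode = c("pairwise", "full")) {
  mode <- match.arg(mode)
  unknown <- setdiff(mirna_ids, network$mirna_degree$id)
  if (length(unknown) > 0) {
    abort(sprintf("unknown miRNA id(s): %s", paste(unknown, collapse = ", ")))
  }
  sets <- lapply(mirna_ids, .targets_of, network = network)
  names(sets) <- mirna_ids

  if (mode == "pairwise") {
    pairs <- utils::combn(mirna_ids, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(p) {
      set_a <- sets[[p[1]]]; set_b <- sets[[p[2]]]
      shared <- sort(intersect(set_a, set_b))
      tibble(a = p[1], b = p[2],
             size_a = length(set_a), size_b = length(set_b),
             n_common = length(shared), common = list(shared))
    })
  } else {
    genes <- sort(unique(unlist(sets)))
    member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
    member <- matrix(member, nrow = length(genes),
                     dimnames = list(genes, mirna_ids))
    region <- apply(member, 1, function(row) paste(mirna_ids[row], collapse = "&"))
    tibble(gene = genes, region = region) |>
      group_by(region = .data$region) |>
      summarise(n = dplyr::n(), members = list(sort(.data$gene)), .groups = "drop") |>
      arrange(.data$region)
  }
}

#' Plot a degree-class abundance table
#'
#' Log-log scatter of degree versus abundance, the standard display for a
#' heavy-tailed degree distribution.
#'
#' @param object A [degree_abundance()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.degree_abundance <- function(object, ...) {
  side <- attr(object, "side", exact = TRUE) %||% "gene"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$degree, y = .data$abundance)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "abundance (nodes with this degree)",
                  title = sprintf("%s degree-class abundance", side)) +
    ggplot2::theme_minimal()
}
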