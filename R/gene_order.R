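#' Signed gene orders
#'
#' A mitochondrial gene order is modelled as a signed (circular)
#' permutation: an ordered list of gene symbols, each carrying a strand
#' sign (+1 forward, -1 reverse).  This is the unit of all
#' rearrangement arithmetic in the package.
#'
#' @param symbols Character vector of gene symbols (no duplicates).
#' @param signs Integer vector of +1/-1, recycled if length 1.
#' @param organism Optional organism identifier.
#' @param circular Logical; circular molecules include the adjacency
#'   between the last and first element.
#' @return An object of class `gene_order`.
#' @examples
#' gene_order(c("ND1", "CYTB", "ND6"), c(1, 1, -1))
#' @export
gene_order <- function(symbols, signs = 1L, organism = NA_character_,
                       circular = TRUE) {
  if (length(symbols) == 0) stop("gene order must be non-empty")
  signs <- as.integer(rep_len(signs, length(symbols)))
  if (!all(signs %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  if (anyDuplicated(symbols)) {
    stop("duplicate gene symbols in order",
         if (!is.na(organism)) paste0(" for ", organism))
  }
  structure(list(organism = organism, circular = isTRUE(circular),
                 symbols = as.character(symbols), signs = signs),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order%s: %d genes, %s>\n",
              if (is.na(x$organism)) "" else paste0(" ", x$organism),
              length(x$symbols),
              if (x$circular) "circular" else "linear"))
  cat(" ", format_order(x), "\n")
  invisible(x)
}

#' @export
length.gene_order <- function(x) length(x$symbols)

#' Format / parse the signed order string
#'
#' The interchange string form writes reverse-strand genes with a
#' leading minus, elements separated by single spaces, e.g.
#' `"ND1 -ND6 CYTB"`.
#'
#' @param order A `gene_order`.
#' @return `format_order()`: a single string.
#' @export
format_order <- function(order) {
  paste(ifelse(order$signs < 0, paste0("-", order$symbols), order$symbols),
        collapse = " ")
}

#' @rdname format_order
#' @param string A signed order string.
#' @inheritParams gene_order
#' @return `parse_order()`: a `gene_order`.
#' @export
parse_order <- function(string, organism = NA_character_, circular = TRUE) {
  toks <- strsplit(trimws(string), "\\s+")[[1]]
  neg <- startsWith(toks, "-")
  gene_order(sub("^-", "", toks), ifelse(neg, -1L, 1L),
             organism = organism, circular = circular)
}

#' Reverse-complement of a gene order
#'
#' Reading the circular molecule from the other strand: element order is
#' reversed and every sign flipped.
#'
#' @param order A `gene_order`.
#' @return A `gene_order`.
#' @export
reverse_complement <- function(order) {
  gene_order(rev(order$symbols), -rev(order$signs),
             organism = order$organism, circular = order$circular)
}

#' Rotate a circular gene order
#'
#' @param order A circular `gene_order`.
#' @param k Number of positions to rotate left (element `k+1` becomes
#'   first).
#' @return A `gene_order`.
#' @export
rotate_order <- function(order, k) {
  n <- length(order$symbols)
  if (!order$circular && k %% n != 0) stop("cannot rotate a linear order")
  idx <- ((seq_len(n) - 1 + k) %% n) + 1
  gene_order(order$symbols[idx], order$signs[idx],
             organism = order$organism, circular = order$circular)
}

#' Anchor a circular gene order onto a reference gene
#'
#' Rotates a circular order so the anchor gene (default `ND1`) comes
#' first on the forward strand.  If the anchor lies on the reverse
#' strand the whole order is reverse-complemented first, so that
#' equivalent circular orders (rotations and reflections of the same
#' molecule) map onto a single canonical string.
#'
#' @param order A circular `gene_order` containing the anchor.
#' @param anchor_symbol Anchor gene symbol.
#' @return The anchored `gene_order`.
#' @examples
#' o <- parse_order("C B D E A")
#' format_order(anchor(o, "A"))  # "A C B D E"
#' @export
anchor <- function(order, anchor_symbol = "ND1") {
  if (!order$circular) stop("anchoring requires a circular order")
  i <- match(anchor_symbol, order$symbols)
  if (is.na(i)) {
    stop(sprintf("anchor gene %s absent from order%s", anchor_symbol,
                 if (is.na(order$organism)) "" else
                   paste0(" of ", order$organism)))
  }
  if (order$signs[i] < 0) {
    order <- reverse_complement(order)
    i <- match(anchor_symbol, order$symbols)
  }
  rotate_order(order, i - 1)
}

#' Drop tRNA genes from an order
#'
#' @param order A `gene_order`.
#' @return A `gene_order` without tRNA elements.
#' @export
drop_trnas <- function(order) {
  keep <- !is_trna(order$symbols)
  if (!any(keep)) stop("order contains only tRNA genes")
  gene_order(order$symbols[keep], order$signs[keep],
             organism = order$organism, circular = order$circular)
}

# Canonical signed-adjacency keys of an order.  The adjacency between
# consecutive elements (x, sx) -> (y, sy) is the same physical junction
# as (-y) -> (-x) read from the other strand; the key is the
# lexicographic minimum of the two spellings.
adjacency_set <- function(order) {
  n <- length(order$symbols)
  if (n < 2) return(character(0))
  i <- seq_len(if (order$circular) n else n - 1L)
  j <- if (order$circular) c(seq_len(n)[-1], 1L) else seq_len(n)[-1]
  sx <- order$signs[i]; sy <- order$signs[j]
  x <- order$symbols[i]; y <- order$symbols[j]
  fwd <- paste0(sx, x, ">", sy, y)
  bwd <- paste0(-sy, y, ">", -sx, x)
  ifelse(fwd <= bwd, fwd, bwd)
}

#' Breakpoint distance between two gene orders
#'
#' The number of signed gene adjacencies of one order that are absent
#' from the other, after restricting both to their shared gene set.  An
#' adjacency `(x, y)` with strand signs is considered present in the
#' other order also when it appears as its full reverse `(-y, -x)`:
#' circular molecules have no intrinsic reading direction.  On equal
#' gene content the measure is symmetric with zero diagonal.
#'
#' @param a,b `gene_order` objects.
#' @return Non-negative integer count of breakpoints.
#' @examples
#' breakpoint_distance(parse_order("A B C D", circular = FALSE),
#'                     parse_order("A B D C", circular = FALSE))  # 2
#' @export
breakpoint_distance <- function(a, b) {
  shared <- intersect(a$symbols, b$symbols)
  if (length(shared) < 2) {
    stop("fewer than two shared genes between orders")
  }
  a <- restrict_order(a, shared)
  b <- restrict_order(b, shared)
  sum(!(adjacency_set(a) %in% adjacency_set(b)))
}

restrict_order <- function(order, symbols) {
  keep <- order$symbols %in% symbols
  gene_order(order$symbols[keep], order$signs[keep],
             organism = order$organism, circular = order$circular)
}

#' Pairwise breakpoint distance matrix
#'
#' @param orders A list of `gene_order` objects (named, or names taken
#'   from the organism field).
#' @return A symmetric numeric matrix with zero diagonal; pairs whose
#'   distance is undefined (fewer than two shared genes) are `NA` with a
#'   warning.
#' @export
distance_matrix <- function(orders) {
  if (length(orders) < 2) stop("need at least two orders")
  nm <- names(orders)
  if (is.null(nm)) nm <- vapply(orders, function(o) o$organism, "")
  if (anyNA(nm) || anyDuplicated(nm)) nm <- paste0("order", seq_along(orders))
  n <- length(orders)
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  failed <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- tryCatch(breakpoint_distance(orders[[i]], orders[[j]]),
                    error = function(e) NA_real_)
      if (is.na(d)) failed <- c(failed, paste0(nm[i], "~", nm[j]))
      m[i, j] <- m[j, i] <- d
    }
  }
  if (length(failed)) {
    warning("undefined distances left NA: ", paste(failed, collapse = ", "),
            call. = FALSE)
  }
  m
}

# Canonical spelling of a signed cluster (ordered tuple): a cluster and
# its full reverse-complement denote the same physical gene stretch.
canonical_cluster <- function(symbols, signs) {
  fwd <- paste(ifelse(signs < 0, paste0("-", symbols), symbols),
               collapse = "|")
  rsym <- rev(symbols); rsgn <- -rev(signs)
  bwd <- paste(ifelse(rsgn < 0, paste0("-", rsym), rsym), collapse = "|")
  # byte-order comparison with "-" remapped after letters, so the
  # forward-strand spelling wins over its reverse-complement when
  # either could lead (independent of the session locale)
  keys <- chartr("-", "~", c(fwd, bwd))
  c(fwd, bwd)[order(keys, method = "radix")[1]]
}

#' Enumerate all gene clusters of an order
#'
#' All contiguous ordered runs of `min_len` or more genes, in canonical
#' orientation (a cluster equals its reverse-complement).  On circular
#' orders, windows wrapping past position 1 are included.
#'
#' @param order A `gene_order` (anchored for cross-organism
#'   comparability).
#' @param min_len,max_len Cluster length bounds (defaults 2 and the
#'   element count).
#' @return Character vector of unique canonical cluster strings, genes
#'   joined by `|`.
#' @export
enumerate_clusters <- function(order, min_len = 2,
                               max_len = length(order$symbols)) {
  n <- length(order$symbols)
  max_len <- min(max_len, n)
  if (min_len > max_len) return(character(0))
  out <- character(0)
  starts <- seq_len(if (order$circular) n else n - min_len + 1L)
  for (s in starts) {
    for (k in seq(min_len, max_len)) {
      if (!order$circular && s + k - 1 > n) break
      idx <- ((s - 1 + seq_len(k) - 1) %% n) + 1
      out <- c(out, canonical_cluster(order$symbols[idx], order$signs[idx]))
    }
  }
  unique(out)
}

#' Prevalence of neighboring gene pairs by phylum
#'
#' For every unordered pair of non-tRNA genes, the percentage of a
#' phylum's organisms in which the two are immediate neighbors (in
#' either orientation) after tRNA genes are ignored.  A pair is marked
#' `opposite_strand` when the neighbors lie on different strands in more
#' than half of the organisms where they are adjacent.
#'
#' @param orders List of `gene_order` objects.
#' @param phylum Character vector of phylum labels, parallel to
#'   `orders`.
#' @param exclude_trna Drop tRNA genes before evaluating adjacency
#'   (default `TRUE`).
#' @return Data frame with columns `phylum`, `gene1`, `gene2`,
#'   `n_adjacent`, `n_organisms`, `prevalence` (percent) and
#'   `opposite_strand`.
#' @export
pair_prevalence <- function(orders, phylum, exclude_trna = TRUE) {
  stopifnot(length(orders) == length(phylum))
  rows <- list()
  for (ph in unique(phylum)) {
    sub <- orders[phylum == ph]
    if (length(sub) == 0) next
    adj <- new.env(parent = emptyenv())
    opp <- new.env(parent = emptyenv())
    for (o in sub) {
      oo <- if (exclude_trna) drop_trnas(o) else o
      n <- length(oo$symbols)
      if (n < 2) next
      i <- seq_len(if (oo$circular) n else n - 1L)
      j <- if (oo$circular) c(seq_len(n)[-1], 1L) else seq_len(n)[-1]
      key <- paste(pmin(oo$symbols[i], oo$symbols[j]),
                   pmax(oo$symbols[i], oo$symbols[j]), sep = "~")
      diffs <- oo$signs[i] != oo$signs[j]
      for (u in unique(key)) {
        assign(u, get0(u, adj, ifnotfound = 0L) + 1L, envir = adj)
        if (any(diffs[key == u])) {
          assign(u, get0(u, opp, ifnotfound = 0L) + 1L, envir = opp)
        }
      }
    }
    keys <- ls(adj)
    if (length(keys) == 0) next
    n_adj <- vapply(keys, function(k) get(k, adj), 0L)
    n_opp <- vapply(keys, function(k) get0(k, opp, ifnotfound = 0L), 0L)
    parts <- strsplit(keys, "~", fixed = TRUE)
    rows[[ph]] <- data.frame(
      phylum = ph,
      gene1 = vapply(parts, `[`, "", 1),
      gene2 = vapply(parts, `[`, "", 2),
      n_adjacent = n_adj,
      n_organisms = length(sub),
      prevalence = 100 * n_adj / length(sub),
      opposite_strand = n_opp / n_adj > 0.5,
      row.names = NULL)
  }
  if (length(rows) == 0) {
    warning("no non-empty phylum", call. = FALSE)
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Most common gene cluster per phylum and cluster length
#'
#' Tallies, for each phylum and each cluster length `k`, the canonical
#' cluster present in the largest share of the phylum's organisms.
#' Ties break lexicographically on the canonical cluster string.
#'
#' @inheritParams pair_prevalence
#' @param min_len,max_len Cluster length range.
#' @return Data frame `phylum`, `length`, `cluster`, `prevalence`.
#' @export
most_common_cluster_by_length <- function(orders, phylum, min_len = 2,
                                          max_len = NULL,
                                          exclude_trna = FALSE) {
  stopifnot(length(orders) == length(phylum))
  rows <- list()
  for (ph in unique(phylum)) {
    sub <- orders[phylum == ph]
    if (length(sub) == 0) next
    per_org <- lapply(sub, function(o) {
      oo <- if (exclude_trna) drop_trnas(o) else o
      mx <- if (is.null(max_len)) length(oo$symbols) else max_len
      enumerate_clusters(oo, min_len = min_len, max_len = mx)
    })
    all_cl <- unlist(per_org)
    if (length(all_cl) == 0) next
    klen <- lengths(strsplit(all_cl, "|", fixed = TRUE))
    tab <- table(cluster = all_cl, k = klen)
    for (k in sort(unique(klen))) {
      counts <- tab[, as.character(k)]
      counts <- counts[counts > 0]
      best <- sort(names(counts)[counts == max(counts)])[1]
      rows[[length(rows) + 1L]] <- data.frame(
        phylum = ph, length = k, cluster = best,
        prevalence = 100 * as.numeric(counts[best]) / length(sub))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Alternating gene-block classification
#'
#' Decomposes the non-tRNA genes of a circular order into circularly
#' merged runs of co-oriented genes ("blocks") and asks whether the
#' molecule shows the alternating organization typical of arthropod
#' mtDNA: at least `min_blocks` blocks, every block holding at least
#' `min_block_size` genes.  Orders with a lone reverse-strand gene
#' (the chordate arrangement, e.g. human `ND6`) are not alternating.
#'
#' @param order A `gene_order`.
#' @param min_blocks Minimum number of circular blocks (default 2).
#' @param min_block_size Minimum genes per block (default 2).
#' @param exclude_trna Drop tRNA genes first (default `TRUE`).
#' @return List with `alternating` (logical) and `blocks`, a data frame
#'   of `sign`, `size` and `members` (pipe-joined symbols).
#' @export
is_alternating_blocks <- function(order, min_blocks = 2, min_block_size = 2,
                                  exclude_trna = TRUE) {
  oo <- if (exclude_trna) drop_trnas(order) else order
  n <- length(oo$symbols)
  r <- rle(oo$signs)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  blocks <- lapply(seq_along(r$lengths), function(b) {
    idx <- seq(starts[b], length.out = r$lengths[b])
    list(sign = r$values[b], members = oo$symbols[idx])
  })
  if (oo$circular && length(blocks) > 1 &&
      blocks[[1]]$sign == blocks[[length(blocks)]]$sign) {
    # circular wrap: first and last runs are one block
    blocks[[1]]$members <- c(blocks[[length(blocks)]]$members,
                             blocks[[1]]$members)
    blocks[[length(blocks)]] <- NULL
  }
  df <- data.frame(
    sign = vapply(blocks, function(b) b$sign, 0L),
    size = vapply(blocks, function(b) length(b$members), 0L),
    members = vapply(blocks, function(b) paste(b$members, collapse = "|"),
                     ""))
  alternating <- nrow(df) >= min_blocks && all(df$size >= min_block_size)
  list(alternating = alternating, blocks = df)
}
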