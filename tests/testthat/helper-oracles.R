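# Independent oracles and small generators used across the suite.

# All permutations of a vector (recursive; fine up to n = 6).
all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}

# Breakpoint-distance oracle via the gene-extremity formalism,
# independent of the package's adjacency-string implementation: a
# forward gene X reads tail->head, a reverse gene head->tail; an
# adjacency is the unordered pair {right extremity of the previous
# gene, left extremity of the next}.
oracle_extremity_adjacencies <- function(symbols, signs, circular) {
  left <- ifelse(signs > 0, paste0(symbols, ".t"), paste0(symbols, ".h"))
  right <- ifelse(signs > 0, paste0(symbols, ".h"), paste0(symbols, ".t"))
  n <- length(symbols)
  i <- seq_len(if (circular) n else n - 1L)
  j <- if (circular) c(seq_len(n)[-1], 1L) else seq_len(n)[-1]
  paste(pmin(right[i], left[j]), pmax(right[i], left[j]))
}

oracle_breakpoint <- function(a, b) {
  shared <- intersect(a$symbols, b$symbols)
  ka <- a$symbols %in% shared
  kb <- b$symbols %in% shared
  adj_a <- oracle_extremity_adjacencies(a$symbols[ka], a$signs[ka],
                                        a$circular)
  adj_b <- oracle_extremity_adjacencies(b$symbols[kb], b$signs[kb],
                                        b$circular)
  sum(!(adj_a %in% adj_b))
}

# Random signed circular order over n symbols.
random_order <- function(n, circular = TRUE) {
  gene_order(sample(paste0("g", seq_len(n))),
             sample(c(-1L, 1L), n, replace = TRUE), circular = circular)
}

# Truth-table oracle for tRNA validation: verdict from (reported,
# tool1 identity or NA, tool2 identity or NA).
oracle_trna_verdict <- function(reported, t1, t2) {
  if ((!is.na(t1) && t1 == reported) || (!is.na(t2) && t2 == reported)) {
    return("validated")
  }
  if (!is.na(t1) && !is.na(t2) && t1 == t2) return("amended")
  "unvalidated"
}

# Exact two-sided Mann-Whitney p by complete enumeration of labelings.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">")) +
    0.5 * sum(outer(xs, ys, "=="))
  obs <- u_stat(x, y)
  m <- mean(pooled)
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  exp_u <- n * length(y) / 2
  mean(abs(us - exp_u) >= abs(obs - exp_u) - 1e-12)
}

# Minimal GenBank-dialect record text for parser tests.
genbank_record <- function(organism = "Testus exampleus",
                           topology = "circular",
                           lineage = "Eukaryota; Metazoa; Chordata; Mammalia; Primates.",
                           features = character(0),
                           definition = "mitochondrion, complete genome.") {
  c(sprintf("LOCUS       TEST0001   16000 bp   DNA   %s   23-JAN-2023",
            topology),
    sprintf("DEFINITION  %s %s", organism, definition),
    "ACCESSION   TEST0001",
    sprintf("  ORGANISM  %s", organism),
    paste0("            ", lineage),
    "FEATURES             Location/Qualifiers",
    features,
    "ORIGIN",
    "//")
}

gb_feature <- function(key, location, ...) {
  quals <- c(...)
  c(sprintf("     %-16s%s", key, location),
    if (length(quals)) paste0("                     ", quals))
}
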