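#' Annotated mitochondrial genome objects
#'
#' Internal data model for one organism's annotated mtDNA: an ordered,
#' stranded feature table plus lineage and QC flags.
#'
#' @param organism Organism identifier.
#' @param features Data frame `symbol`, `category`, `strand` (+1/-1),
#'   `start`, `end` (0-based half-open), `anticodon` (NA except tRNA),
#'   sorted by `start`.
#' @param lineage Named character vector (at least `phylum`, `class`,
#'   `order`), possibly `NA`.
#' @param topology `"circular"` or `"linear"`.
#' @param flags Character subset of `c("fragmented", "incomplete",
#'   "has_cds_introns", "has_unvalidated_trna", "missing_lineage")`.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(organism, features,
                             lineage = c(phylum = NA, class = NA,
                                         order = NA),
                             topology = "circular",
                             flags = character(0)) {
  stopifnot(all(c("symbol", "category", "strand", "start", "end") %in%
                  names(features)),
            all(features$start < features$end),
            topology %in% c("circular", "linear"))
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  if (!"anticodon" %in% names(features)) features$anticodon <- NA_character_
  structure(list(organism = organism, lineage = lineage,
                 topology = topology, features = features,
                 flags = unique(flags)),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome %s: %d features, %s%s>\n", x$organism,
              nrow(x$features), x$topology,
              if (length(x$flags))
                paste0("; flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Signed gene order of an annotated genome
#'
#' @param genome An [annotated_genome()].
#' @param exclude_trna Drop tRNA features.
#' @return A [gene_order()] (features with duplicated symbols raise an
#'   error; such genomes are excluded upstream).
#' @export
genome_order <- function(genome, exclude_trna = FALSE) {
  f <- genome$features
  if (exclude_trna) f <- f[f$category != "tRNA", , drop = FALSE]
  gene_order(f$symbol, f$strand, organism = genome$organism,
             circular = genome$topology == "circular")
}

# ---- GenBank-dialect flat-file reader -----------------------------------
#
# Parses the subset of the GenBank feature-table dialect needed for
# annotated organelle records: LOCUS (id, topology), DEFINITION,
# ORGANISM with its lineage paragraph, and CDS/tRNA/rRNA features with
# location (1-based inclusive, complement(), join(), <,> partial
# markers) and /gene, /product, /anticodon qualifiers.

parse_location <- function(loc) {
  strand <- if (grepl("complement", loc)) -1L else 1L
  partial <- grepl("[<>]", loc)
  segs <- regmatches(loc, gregexpr("[0-9]+\\.\\.[0-9]+", loc))[[1]]
  if (length(segs) == 0) return(NULL)
  bounds <- do.call(rbind, lapply(strsplit(segs, "..", fixed = TRUE),
                                  as.numeric))
  list(start = min(bounds[, 1]) - 1,  # to 0-based half-open
       end = max(bounds[, 2]),
       strand = strand, partial = partial,
       joined = length(segs) > 1)
}

parse_one_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  topology <- if (!is.na(locus) && grepl("circular", locus)) "circular"
              else "linear"
  organism <- sub("^\\s*ORGANISM\\s+", "",
                  grep("^\\s*ORGANISM", lines, value = TRUE)[1])
  if (is.na(organism)) {
    acc <- grep("^ACCESSION", lines, value = TRUE)[1]
    organism <- if (is.na(acc)) NA_character_ else
      strsplit(trimws(sub("^ACCESSION", "", acc)), "\\s+")[[1]][1]
  }
  # lineage paragraph: indented lines after ORGANISM up to the next key
  lineage <- c(phylum = NA_character_, class = NA_character_,
               order = NA_character_)
  oi <- grep("^\\s*ORGANISM", lines)
  if (length(oi)) {
    j <- oi[1] + 1
    lin <- character(0)
    while (j <= length(lines) && grepl("^\\s{8,}", lines[j])) {
      lin <- c(lin, trimws(lines[j])); j <- j + 1
    }
    taxa <- trimws(strsplit(gsub("\\.$", "", paste(lin, collapse = " ")),
                            ";")[[1]])
    # metazoan convention: ...; Metazoa; <phylum>; <class>; <order>; ...
    mi <- match("Metazoa", taxa)
    if (!is.na(mi) && length(taxa) >= mi + 1) {
      got <- taxa[seq(mi + 1, min(mi + 3, length(taxa)))]
      lineage[seq_along(got)] <- got
    }
  }
  fstart <- grep("^FEATURES", lines)
  feats <- list(); flags <- character(0); errors <- character(0)
  if (length(fstart)) {
    i <- fstart[1] + 1
    while (i <= length(lines)) {
      ln <- lines[i]
      if (grepl("^(ORIGIN|CONTIG|//)", ln)) break
      m <- regmatches(ln, regexec("^\\s{5}(\\S+)\\s+(\\S+)", ln))[[1]]
      if (length(m) == 3 && m[2] %in% c("CDS", "tRNA", "rRNA")) {
        key <- m[2]; loc_str <- m[3]
        quals <- character(0)
        j <- i + 1
        while (j <= length(lines) &&
               grepl("^\\s{10,}", lines[j]) &&
               !grepl("^\\s{5}\\S", lines[j])) {
          quals <- c(quals, trimws(lines[j])); j <- j + 1
        }
        loc <- parse_location(loc_str)
        if (is.null(loc)) {
          errors <- c(errors, paste0("unparseable location for ", key,
                                     " at line ", i))
        } else {
          getq <- function(name) {
            hit <- grep(paste0("^/", name, "="), quals, value = TRUE)[1]
            if (is.na(hit)) NA_character_ else
              gsub("\"", "", sub(paste0("^/", name, "="), "", hit))
          }
          label <- getq("gene")
          if (is.na(label)) label <- getq("product")
          anticodon <- NA_character_
          ac <- getq("anticodon")
          if (!is.na(ac)) {
            seqm <- regmatches(ac, regexec("seq:([acgtuACGTU]+)", ac))[[1]]
            if (length(seqm) == 2) {
              anticodon <- chartr("Uu", "Tt", toupper(seqm[2]))
            }
          }
          if (is.na(label)) {
            errors <- c(errors, paste0("feature ", key, " at line ", i,
                                       " lacks gene/product"))
          } else {
            if (loc$partial) flags <- c(flags, "incomplete")
            if (key == "CDS" && loc$joined) {
              flags <- c(flags, "has_cds_introns")
            }
            feats[[length(feats) + 1]] <- data.frame(
              raw = label,
              category = c(CDS = "PCG", tRNA = "tRNA",
                           rRNA = "rRNA")[key],
              strand = loc$strand, start = loc$start, end = loc$end,
              anticodon = anticodon)
          }
        }
        i <- j
      } else {
        i <- i + 1
      }
    }
  }
  def <- grep("^DEFINITION", lines, value = TRUE)[1]
  if (!is.na(def) && grepl("partial", def, ignore.case = TRUE)) {
    flags <- c(flags, "incomplete")
  }
  list(organism = organism, topology = topology, lineage = lineage,
       features = if (length(feats))
         do.call(rbind, c(feats, make.row.names = FALSE)) else NULL,
       flags = unique(flags), errors = errors)
}

#' Parse GenBank-dialect flat files into annotated genomes
#'
#' Reads one or more records (separated by `//`), converts the 1-based
#' inclusive coordinates to the internal 0-based half-open convention,
#' maps raw gene labels through the shipped synonym table (unknown
#' labels pass through verbatim with a warning) and resolves the
#' ambiguous tRNA-Leu/tRNA-Ser labels by anticodon where one is
#' annotated.  Malformed features are logged per record and parsing
#' continues.  Organisms listed more than once are flagged
#' `fragmented`; organisms with no resolvable lineage are flagged
#' `missing_lineage`, not dropped.
#'
#' @param path Path to a flat file, or a character vector of its lines.
#' @param lineage_table Optional data frame `organism`, `phylum`,
#'   `class`, `order` overriding/supplying lineages.
#' @return List with `genomes` (list of [annotated_genome()]) and
#'   `errors` (data frame `organism`, `message`).
#' @export
parse_genomes <- function(path, lineage_table = NULL) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path)
           else path
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "//")))
  genomes <- list(); errlog <- list()
  for (rec in recs) {
    if (!any(grepl("^LOCUS", rec))) next
    p <- parse_one_record(rec)
    for (e in p$errors) {
      errlog[[length(errlog) + 1]] <- data.frame(
        organism = p$organism, message = e)
    }
    if (is.null(p$features)) {
      errlog[[length(errlog) + 1]] <- data.frame(
        organism = p$organism, message = "no usable features")
      next
    }
    sym <- canonical_symbol(p$features$raw)
    # disambiguate the two Leu/Ser isoacceptors by anticodon
    amb <- sym %in% c("trnL", "trnS") & !is.na(p$features$anticodon)
    if (any(amb)) {
      iso <- ifelse(sym[amb] == "trnL",
                    ifelse(p$features$anticodon[amb] == "TAG", "1", "2"),
                    ifelse(p$features$anticodon[amb] == "GCT", "1", "2"))
      sym[amb] <- paste0(sym[amb], iso)
    }
    features <- data.frame(symbol = sym,
                           category = p$features$category,
                           strand = p$features$strand,
                           start = p$features$start,
                           end = p$features$end,
                           anticodon = p$features$anticodon)
    lineage <- p$lineage
    flags <- p$flags
    if (!is.null(lineage_table)) {
      hit <- match(p$organism, lineage_table$organism)
      if (!is.na(hit)) {
        lineage <- c(phylum = lineage_table$phylum[hit],
                     class = lineage_table$class[hit],
                     order = lineage_table$order[hit])
      }
    }
    if (all(is.na(lineage))) flags <- c(flags, "missing_lineage")
    if (p$organism %in% names(genomes)) {
      # multi-record organism: fragmented molecule
      genomes[[p$organism]]$flags <-
        unique(c(genomes[[p$organism]]$flags, "fragmented"))
      next
    }
    genomes[[p$organism]] <- annotated_genome(
      p$organism, features, lineage = lineage, topology = p$topology,
      flags = unique(flags))
  }
  list(genomes = genomes,
       errors = if (length(errlog))
         do.call(rbind, c(errlog, make.row.names = FALSE)) else
           data.frame(organism = character(), message = character()))
}

# ---- tRNA cross-validation ----------------------------------------------

span_overlap_ok <- function(s1, e1, s2, e2, min_frac = 0.5) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  ov >= min_frac * (e1 - s1) && ov >= min_frac * (e2 - s2)
}

#' Cross-validate reported tRNA annotations against two predictors
#'
#' For every reported tRNA feature the two prediction tables (as
#' produced by independent tRNA-finding tools, consumed here as
#' tabular input) are searched for a locus match — at least 50%
#' reciprocal span overlap by default.  The verdict is:
#'
#' * `validated` — at least one tool confirms the reported identity;
#' * `amended` — both tools locate the tRNA and agree on an identity
#'   different from the reported one (the annotation is amended);
#' * `unvalidated` — neither tool locates a tRNA there, or the tools
#'   disagree with each other.
#'
#' The genome gains the `has_unvalidated_trna` flag iff any verdict is
#' `unvalidated`.
#'
#' @param genome An [annotated_genome()].
#' @param predictions Data frame `organism`, `tool`, `identity`,
#'   `start`, `end`, `strand` covering exactly two tool labels
#'   (possibly with zero rows for a tool).
#' @param min_overlap Reciprocal span-overlap fraction for locus
#'   matching (default 0.5).
#' @return List with `genome` (flags and symbols updated) and
#'   `verdicts` (data frame `symbol`, `start`, `end`, `verdict`,
#'   `identity`).
#' @export
validate_trnas <- function(genome, predictions, min_overlap = 0.5) {
  stopifnot(all(c("organism", "tool", "identity", "start", "end") %in%
                  names(predictions)))
  preds <- predictions[predictions$organism == genome$organism, ,
                       drop = FALSE]
  if (nrow(predictions) > 0 && nrow(preds) == 0 &&
      !genome$organism %in% predictions$organism) {
    stop("prediction set does not cover organism ", genome$organism)
  }
  tools <- sort(unique(predictions$tool))
  if (length(tools) != 2) {
    stop("predictions must carry exactly two tool labels")
  }
  f <- genome$features
  ti <- which(f$category == "tRNA")
  verdicts <- list()
  for (i in ti) {
    found <- vapply(tools, function(tl) {
      sub <- preds[preds$tool == tl, , drop = FALSE]
      hit <- which(vapply(seq_len(nrow(sub)), function(r) {
        span_overlap_ok(f$start[i], f$end[i], sub$start[r], sub$end[r],
                        min_overlap)
      }, FALSE))
      if (length(hit) == 0) NA_character_ else sub$identity[hit[1]]
    }, "")
    reported <- f$symbol[i]
    if (any(!is.na(found) & found == reported)) {
      verdict <- "validated"; identity <- reported
    } else if (!anyNA(found) && found[1] == found[2]) {
      verdict <- "amended"; identity <- found[1]
      f$symbol[i] <- identity
    } else {
      verdict <- "unvalidated"; identity <- NA_character_
    }
    verdicts[[length(verdicts) + 1]] <- data.frame(
      symbol = reported, start = f$start[i], end = f$end[i],
      verdict = verdict, identity = identity)
  }
  vdf <- if (length(verdicts))
    do.call(rbind, c(verdicts, make.row.names = FALSE)) else
      data.frame(symbol = character(), start = numeric(),
                 end = numeric(), verdict = character(),
                 identity = character())
  genome$features <- f
  if (any(vdf$verdict == "unvalidated")) {
    genome$flags <- unique(c(genome$flags, "has_unvalidated_trna"))
  }
  list(genome = genome, verdicts = vdf)
}

#' Quality filter over annotated genomes
#'
#' Excludes genomes whose flags intersect `{fragmented, incomplete,
#' has_cds_introns, has_unvalidated_trna}`; set semantics, so the
#' filter is idempotent and order-independent.
#'
#' @param genomes List of [annotated_genome()] objects.
#' @return List with `admitted` (sub-list) and `report` (data frame
#'   `organism`, `flags` of exclusions).
#' @export
qc_filter <- function(genomes) {
  blocking <- c("fragmented", "incomplete", "has_cds_introns",
                "has_unvalidated_trna")
  bad <- vapply(genomes, function(g) any(g$flags %in% blocking), FALSE)
  report <- if (any(bad)) {
    do.call(rbind, lapply(genomes[bad], function(g) {
      data.frame(organism = g$organism,
                 flags = paste(intersect(g$flags, blocking),
                               collapse = ","))
    }))
  } else {
    data.frame(organism = character(), flags = character())
  }
  rownames(report) <- NULL
  list(admitted = genomes[!bad], report = report)
}

# ---- genome table (interchange TSV) -------------------------------------

#' Read and write the genome interchange table
#'
#' The tab-separated "genome table" is the interchange format all
#' downstream modules accept: one row per organism with lineage,
#' topology, the signed gene-order string and QC flags.  Writing then
#' re-reading reproduces the table field-for-field.
#'
#' @param genomes List of [annotated_genome()] objects (for
#'   `genome_table()`), or a genome-table data frame (for
#'   `write_genome_table()`).
#' @return `genome_table()`: data frame `organism`, `phylum`, `class`,
#'   `order`, `topology`, `gene_order`, `flags`.
#' @export
genome_table <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    data.frame(organism = g$organism,
               phylum = unname(g$lineage["phylum"]),
               class = unname(g$lineage["class"]),
               order = unname(g$lineage["order"]),
               topology = g$topology,
               gene_order = format_order(genome_order(g)),
               flags = paste(g$flags, collapse = ","))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' @rdname genome_table
#' @param table A genome-table data frame.
#' @param path File path.
#' @export
write_genome_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname genome_table
#' @export
read_genome_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  out$flags[is.na(out$flags)] <- ""
  out
}

#' Gene orders from a genome table
#'
#' @param table A genome-table data frame.
#' @return Named list of [gene_order()] objects.
#' @export
table_orders <- function(table) {
  setNames(lapply(seq_len(nrow(table)), function(i) {
    parse_order(table$gene_order[i], organism = table$organism[i],
                circular = table$topology[i] == "circular")
  }), table$organism)
}
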