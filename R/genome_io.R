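#' Read an annotated bacterial genome from a GenBank flat file
#'
#' Parses every record of a GenBank flat file and returns one gene entry per
#' CDS feature. Coordinates are converted from GenBank's 1-based inclusive
#' convention to 0-based half-open intervals, so `end - start` is the gene
#' length and intervals are directly BED-compatible.
#'
#' EC numbers are harvested both from `/EC_number` qualifiers and from
#' `EC x.y.z.w` patterns embedded in the `/product` text. Compound (`join`)
#' locations are flattened to their outer span, which preserves the only
#' information the divergence screen uses: orientation and intergenic
#' distance. Pseudo-genes and non-CDS features are ignored.
#'
#' @param path Path to a GenBank flat file with one or more records.
#' @return An object of class `genome_annotation`: a list with
#'   \describe{
#'     \item{replicons}{data.frame with `replicon_id` and `length` (bp).}
#'     \item{genes}{data.frame with one row per CDS: `gene_id`,
#'       `replicon_id`, `start`, `end` (0-based half-open), `strand`
#'       (`"+"`/`"-"`), `product`, `ec_numbers` (list column of character
#'       vectors), `is_tr` (logical, `NA` until [detect_tr_genes()] runs),
#'       `tr_family`.}
#'     \item{sequences}{named list of nucleotide strings (may be empty when
#'       the record carries no ORIGIN block).}
#'   }
#' @seealso [detect_tr_genes()], [infer_operons()], [write_candidates()]
#' @export
read_annotated_genome <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read genome file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines))) {
    stop("not a GenBank flat file (no LOCUS line): ", path)
  }
  rec_starts <- grep("^LOCUS", lines)
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))

  replicons <- list()
  gene_rows <- list()
  sequences <- list()

  for (r in seq_along(rec_starts)) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    parsed <- parse_genbank_record(rec)
    replicons[[r]] <- data.frame(
      replicon_id = parsed$replicon_id,
      length = parsed$length,
      stringsAsFactors = FALSE
    )
    if (nrow(parsed$genes) == 0L) {
      warning("record ", parsed$replicon_id, " contains no CDS features")
    } else {
      gene_rows[[length(gene_rows) + 1L]] <- parsed$genes
    }
    if (!is.null(parsed$sequence)) {
      sequences[[parsed$replicon_id]] <- parsed$sequence
    }
  }

  genes <- if (length(gene_rows)) {
    do.call(rbind, gene_rows)
  } else {
    empty_gene_table()
  }
  genes <- genes[order(genes$replicon_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  structure(
    list(
      replicons = do.call(rbind, replicons),
      genes = genes,
      sequences = sequences
    ),
    class = "genome_annotation"
  )
}

empty_gene_table <- function() {
  df <- data.frame(
    gene_id = character(), replicon_id = character(),
    start = integer(), end = integer(), strand = character(),
    product = character(), stringsAsFactors = FALSE
  )
  df$ec_numbers <- list()
  df$is_tr <- logical()
  df$tr_family <- character()
  df
}

# One GenBank record (LOCUS .. //) -> replicon id/length, CDS table, sequence.
parse_genbank_record <- function(rec) {
  locus <- strsplit(trimws(rec[1]), "[[:space:]]+")[[1]]
  replicon_id <- locus[2]
  length_bp <- suppressWarnings(as.integer(locus[3]))

  feat_i <- grep("^FEATURES", rec)
  origin_i <- grep("^ORIGIN", rec)
  end_i <- if (length(origin_i)) origin_i[1] - 1L else length(rec)

  genes <- empty_gene_table()
  if (length(feat_i)) {
    feat_lines <- rec[(feat_i[1] + 1L):end_i]
    feat_lines <- feat_lines[!grepl("^(CONTIG|BASE COUNT|//)", feat_lines)]
    # feature keys start at column 6; qualifiers/continuations at column 22
    key_idx <- grep("^ {5}\\S", feat_lines)
    if (length(key_idx)) {
      key_end <- c(key_idx[-1] - 1L, length(feat_lines))
      rows <- list()
      for (k in seq_along(key_idx)) {
        block <- feat_lines[key_idx[k]:key_end[k]]
        key <- sub("^ {5}(\\S+).*", "\\1", block[1])
        if (key != "CDS") next
        g <- parse_cds_feature(block, replicon_id)
        if (!is.null(g)) rows[[length(rows) + 1L]] <- g
      }
      if (length(rows)) genes <- do.call(rbind, rows)
    }
  }

  sequence <- NULL
  if (length(origin_i)) {
    seq_lines <- rec[(origin_i[1] + 1L):length(rec)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(sequence)) sequence <- NULL
  }
  if (is.na(length_bp) && !is.null(sequence)) length_bp <- nchar(sequence)

  list(replicon_id = replicon_id, length = length_bp,
       genes = genes, sequence = sequence)
}

parse_cds_feature <- function(block, replicon_id) {
  # location: first-line remainder plus continuation lines up to the first
  # qualifier
  qual_start <- grep("^ {21}/", block)
  loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
  loc <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", block[1]),
                        if (loc_end >= 2L) block[2:loc_end] else character())),
               collapse = "")

  quals <- if (length(qual_start)) {
    parse_qualifiers(block[qual_start[1]:length(block)])
  } else {
    character()
  }
  if ("pseudo" %in% names(quals)) return(NULL)

  span <- parse_location(loc)
  if (is.null(span)) return(NULL)
  if (span$compound) {
    warning("compound location flattened to outer span: ", loc)
  }

  product <- qual1(quals, "product") %||% ""
  ecs <- unique(c(
    quals_all(quals, "EC_number"),
    regmatches(product, gregexpr("EC[ :]?([0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+)",
                                 product))[[1]]
  ))
  ecs <- sub("^EC[ :]?", "", ecs)
  ecs <- ecs[nzchar(ecs)]

  gene_id <- qual1(quals, "locus_tag") %||% qual1(quals, "gene") %||%
    paste0("cds_", span$start)

  df <- data.frame(
    gene_id = gene_id, replicon_id = replicon_id,
    start = span$start, end = span$end, strand = span$strand,
    product = product, stringsAsFactors = FALSE
  )
  df$ec_numbers <- list(ecs)
  df$is_tr <- NA
  df$tr_family <- NA_character_
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

qual1 <- function(quals, name) {
  hit <- which(names(quals) == name)
  if (length(hit)) unname(quals[hit[1]]) else NULL
}

# Qualifier lines -> named character vector (duplicates kept, names repeated).
parse_qualifiers <- function(lines) {
  if (!length(lines)) return(character())
  starts <- grep("^ {21}/", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- character()
  nms <- character()
  for (i in seq_along(starts)) {
    txt <- paste(trimws(lines[starts[i]:ends[i]]), collapse = " ")
    txt <- sub("^/", "", txt)
    if (grepl("=", txt)) {
      nm <- sub("=.*$", "", txt)
      val <- sub("^[^=]*=", "", txt)
      val <- gsub("^\"|\"$", "", val)
    } else {
      nm <- txt
      val <- ""
    }
    nms <- c(nms, nm)
    out <- c(out, val)
  }
  names(out) <- nms
  out
}

quals_all <- function(quals, name) unname(quals[names(quals) == name])

# GenBank location string -> 0-based half-open outer span + strand.
parse_location <- function(loc) {
  strand <- "+"
  compound <- grepl("join|order", loc)
  if (grepl("complement", loc)) strand <- "-"
  loc <- gsub("[<>]", "", loc)
  pos <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (length(pos) < 1L) return(NULL)
  pos <- as.integer(pos)
  list(start = min(pos) - 1L, end = max(pos), strand = strand,
       compound = compound)
}

#' Write candidate inducible systems to tabular files
#'
#' Serialises candidates (from [assemble_candidates()]) to a tab-separated
#' table, one row per candidate, and optionally a headerless BED file of the
#' promoter intervals (0-based half-open, as stored).
#'
#' @param candidates data.frame from [assemble_candidates()].
#' @param path Output TSV path.
#' @param bed_path Optional path for a BED file of promoter intervals.
#' @return Invisibly, the table that was written.
#' @export
write_candidates <- function(candidates, path, bed_path = NULL) {
  tab <- data.frame(
    tr_gene_id = character(), tr_family = character(),
    replicon_id = character(), promoter_start = integer(),
    promoter_end = integer(), promoter_length = integer(),
    operon_genes = character(), status = character(),
    reason = character(), ligands = character(),
    stringsAsFactors = FALSE
  )
  if (!is.null(candidates) && nrow(candidates)) {
    tab <- data.frame(
      tr_gene_id = candidates$tr_gene_id,
      tr_family = candidates$tr_family,
      replicon_id = candidates$replicon_id,
      promoter_start = candidates$promoter_start,
      promoter_end = candidates$promoter_end,
      promoter_length = candidates$promoter_end - candidates$promoter_start,
      operon_genes = vapply(candidates$operon_genes, paste,
                            character(1), collapse = ","),
      status = candidates$status,
      reason = candidates$reason,
      ligands = vapply(candidates$ligands, function(lg) {
        if (is.null(lg) || nrow(lg) == 0L) return("")
        paste(sprintf("%s(consumed:%d,produced:%d)", lg$compound,
                      lg$consumed_by, lg$produced_by), collapse = ";")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write candidate table to: ", path)

  if (!is.null(bed_path) && nrow(tab)) {
    bed <- data.frame(tab$replicon_id, tab$promoter_start, tab$promoter_end,
                      paste0(tab$tr_gene_id, "_promoter"))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tab)
}

#' Read a candidate table written by [write_candidates()]
#'
#' @param path Path to the TSV file.
#' @return data.frame with the flattened candidate fields.
#' @export
read_candidates <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(reason = "character",
                                   ligands = "character",
                                   operon_genes = "character"))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$replicons), "replicon(s),",
      nrow(x$genes), "CDS\n")
  invisible(x)
}
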