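#' Default transcriptional-regulator product lexicon
#'
#' Case-insensitive patterns matched against CDS product text, mapped to a
#' family label. Generic regulator phrases map to family `"unknown"` unless a
#' family token also matches.
#'
#' @return data.frame with `pattern` and `family` columns.
#' @export
default_tr_lexicon <- function() {
  fam <- c("LysR", "MarR", "AsnC", "MocR", "IclR", "TetR", "AraC", "GntR",
           "LacI", "XRE")
  rbind(
    data.frame(pattern = fam, family = fam, stringsAsFactors = FALSE),
    data.frame(
      pattern = c("sigma-54 dependent", "sigma 54 dependent",
                  "transcriptional regulator", "transcriptional activator",
                  "transcriptional repressor", "transcription factor"),
      family = c("sigma54", "sigma54", "unknown", "unknown", "unknown",
                 "unknown"),
      stringsAsFactors = FALSE
    )
  )
}

#' Flag transcriptional-regulator genes by product annotation
#'
#' Marks each gene whose product description matches any pattern in the
#' lexicon as a TR and records the first matching family token (families are
#' tried before the generic regulator phrases, so "LysR family
#' transcriptional regulator" is classified LysR, not unknown).
#'
#' @param annotation `genome_annotation` from [read_annotated_genome()].
#' @param lexicon data.frame of `pattern`/`family`; default
#'   [default_tr_lexicon()].
#' @return The annotation with `is_tr` and `tr_family` filled.
#' @export
detect_tr_genes <- function(annotation, lexicon = default_tr_lexicon()) {
  stopifnot(nrow(lexicon) > 0)
  genes <- annotation$genes
  genes$is_tr <- rep(FALSE, nrow(genes))
  genes$tr_family <- rep(NA_character_, nrow(genes))
  if (nrow(genes)) {
    for (i in seq_len(nrow(lexicon))) {
      hit <- grepl(lexicon$pattern[i], genes$product, ignore.case = TRUE)
      newly <- hit & !genes$is_tr
      genes$is_tr[hit] <- TRUE
      genes$tr_family[newly] <- lexicon$family[i]
    }
  }
  annotation$genes <- genes
  annotation
}

#' Infer operons as maximal same-strand gene runs
#'
#' Groups consecutive co-directional genes whose intergenic gaps do not
#' exceed `max_gap` into candidate operons. TR genes never join an operon
#' (and never contribute to its catalytic-gene count): the screen treats
#' them as the regulator, not the regulated pathway. Single-gene runs are
#' kept; the minimum-catalytic-genes rule is applied later by
#' [assemble_candidates()].
#'
#' @param annotation `genome_annotation` with `is_tr` filled
#'   (see [detect_tr_genes()]).
#' @param max_gap Maximum intergenic distance (bp) between co-transcribed
#'   genes; default 150.
#' @return data.frame with one row per operon: `operon_id`, `replicon_id`,
#'   `strand`, `start`, `end`, `genes` (list column of gene ids in
#'   transcription order), `n_catalytic`.
#' @export
infer_operons <- function(annotation, max_gap = 150) {
  stopifnot(max_gap >= 0)
  genes <- annotation$genes
  out <- list()
  for (rep_id in unique(genes$replicon_id)) {
    g <- genes[genes$replicon_id == rep_id & !is_true(genes$is_tr), ,
               drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (!nrow(g)) next
    run_id <- cumsum(c(1L, (g$strand[-1] != g$strand[-nrow(g)]) |
                            (g$start[-1] - g$end[-nrow(g)] > max_gap)))
    # an interposed opposite-strand gene breaks a run even when gaps across
    # it are small: runs are over adjacent genes in genomic order
    for (rid in unique(run_id)) {
      run <- g[run_id == rid, , drop = FALSE]
      run <- run[order(run$start, decreasing = run$strand[1] == "-"), ,
                 drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        replicon_id = rep_id,
        strand = run$strand[1],
        start = min(run$start),
        end = max(run$end),
        n_genes = nrow(run),
        n_catalytic = sum(is_catalytic(run)),
        stringsAsFactors = FALSE
      )
      out[[length(out)]]$genes <- list(run$gene_id)
    }
  }
  if (!length(out)) {
    res <- data.frame(replicon_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_genes = integer(), n_catalytic = integer(),
                      stringsAsFactors = FALSE)
    res$genes <- list()
    res$operon_id <- character()
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicon_id, res$start), , drop = FALSE]
  res$operon_id <- sprintf("operon_%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

is_true <- function(x) !is.na(x) & x

# "Annotated catalytic function": >=1 EC number, or a catalytic product
# keyword (enzyme-class suffixes).
catalytic_pattern <- paste0(
  "(dehydrogenase|decarboxylase|transferase|hydrolase|oxidase|reductase|",
  "synthase|synthetase|kinase|lyase|isomerase|ligase|mutase|aminase|",
  "carboxylase|aldolase|esterase|peptidase|protease|phosphatase|",
  "monooxygenase|dioxygenase|hydratase|dehydratase|deaminase|epimerase|",
  "racemase|amidase|oxygenase)")

is_catalytic <- function(genes) {
  has_ec <- vapply(genes$ec_numbers, length, integer(1)) > 0
  has_kw <- grepl(catalytic_pattern, genes$product, ignore.case = TRUE)
  (has_ec | has_kw) & !is_true(genes$is_tr)
}

#' Find divergent TR / operon pairs with their shared promoter region
#'
#' For every TR gene, pairs it with operons on the opposite strand whose
#' first (5') gene lies head-to-head with the TR across an intergenic region
#' of at most `max_intergenic` bp. In a divergent arrangement the 5' ends
#' face each other: a minus-strand TR is paired with a plus-strand operon
#' starting to its right, and vice versa. Convergent and co-directional
#' arrangements are excluded, as are overlapping TR/operon genes (negative
#' intergenic length). When a TR has eligible divergent operons on both
#' sides, both pairs are emitted, ranked by smaller intergenic distance.
#'
#' The promoter interval is the gap between the TR gene and the operon's
#' first gene (0-based half-open); by construction it overlaps neither CDS.
#'
#' @param annotation `genome_annotation` with `is_tr` filled.
#' @param operons Operon table from [infer_operons()].
#' @param max_intergenic Maximum promoter length in bp; default 500.
#' @return data.frame with `tr_gene_id`, `tr_family`, `operon_id`,
#'   `replicon_id`, `promoter_start`, `promoter_end`, `intergenic_length`,
#'   plus the operon's `strand`, `n_catalytic` and `genes` list column.
#' @export
find_divergent_candidates <- function(annotation, operons,
                                      max_intergenic = 500) {
  genes <- annotation$genes
  trs <- genes[is_true(genes$is_tr), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(trs))) {
    tr <- trs[i, ]
    ops <- operons[operons$replicon_id == tr$replicon_id &
                     operons$strand != tr$strand, , drop = FALSE]
    if (!nrow(ops)) next
    for (j in seq_len(nrow(ops))) {
      op <- ops[j, ]
      # divergent: 5' ends face each other across the gap
      if (tr$strand == "-" && op$strand == "+" && op$start >= tr$end) {
        p_start <- tr$end; p_end <- op$start
      } else if (tr$strand == "+" && op$strand == "-" && tr$start >= op$end) {
        p_start <- op$end; p_end <- tr$start
      } else {
        next
      }
      len <- p_end - p_start
      if (len < 0 || len > max_intergenic) next
      # require adjacency: no other CDS inside the putative promoter
      inside <- genes$replicon_id == tr$replicon_id &
        genes$start < p_end & genes$end > p_start
      if (any(inside)) next
      rows[[length(rows) + 1L]] <- data.frame(
        tr_gene_id = tr$gene_id,
        tr_family = tr$tr_family,
        operon_id = op$operon_id,
        replicon_id = tr$replicon_id,
        strand = op$strand,
        promoter_start = p_start,
        promoter_end = p_end,
        intergenic_length = len,
        n_catalytic = op$n_catalytic,
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$operon_genes <- op$genes
    }
  }
  if (!length(rows)) {
    res <- data.frame(tr_gene_id = character(), tr_family = character(),
                      operon_id = character(), replicon_id = character(),
                      strand = character(), promoter_start = integer(),
                      promoter_end = integer(), intergenic_length = integer(),
                      n_catalytic = integer(), stringsAsFactors = FALSE)
    res$operon_genes <- list()
    return(res)
  }
  res <- do.call(rbind, rows)
  # per TR keep pairs ranked by intergenic distance
  res <- res[order(res$tr_gene_id, res$intergenic_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract the promoter interval (and sequence) of a divergent pair
#'
#' Returns the stored intergenic interval; when the parsed record carries
#' nucleotide sequence, also the promoter sequence reported on the operon's
#' coding strand (reverse complement of the genomic top strand for
#' minus-strand operons).
#'
#' @param pair One row of the [find_divergent_candidates()] table.
#' @param annotation The `genome_annotation` the pair came from.
#' @return list with `replicon_id`, `start`, `end`, `length`, and `sequence`
#'   (`NULL` when the record has none).
#' @export
extract_promoter_region <- function(pair, annotation) {
  rep_len <- annotation$replicons$length[
    annotation$replicons$replicon_id == pair$replicon_id]
  if (!length(rep_len) || pair$promoter_start < 0 ||
      pair$promoter_end > rep_len) {
    stop("promoter interval outside replicon bounds")
  }
  len <- pair$promoter_end - pair$promoter_start
  if (len == 0L) warning("zero-length intergenic region (abutting genes)")
  seq <- NULL
  full <- annotation$sequences[[pair$replicon_id]]
  if (!is.null(full) && len > 0L) {
    seq <- substr(full, pair$promoter_start + 1L, pair$promoter_end)
    if (pair$strand == "-") seq <- revcomp(seq)
  }
  list(replicon_id = pair$replicon_id, start = pair$promoter_start,
       end = pair$promoter_end, length = len, sequence = seq)
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
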