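#' Default cofactor blacklist
#'
#' Ubiquitous co-substrates removed before inferring the pathway entry
#' compound; without this, water or NAD+ would frequently appear as a
#' spurious graph source.
#'
#' @return character vector of normalised compound identifiers.
#' @export
default_cofactor_blacklist <- function() {
  c("h2o", "water", "h+", "proton", "atp", "adp", "amp",
    "nad+", "nadh", "nadp+", "nadph", "coa", "coenzyme a",
    "phosphate", "diphosphate", "pi", "ppi", "co2", "o2", "oxygen",
    "nh3", "ammonia")
}

#' Load a reaction knowledgebase from a TSV file
#'
#' The file must have columns `ec`, `substrates`, `products`, `reversible`,
#' with substrates/products `;`-delimited. Compound identifiers are
#' case-normalised (lower case, trimmed). Duplicate (ec, substrates,
#' products) rows are deduplicated with a warning. This table-structured
#' knowledgebase plays the role an enzyme database (e.g. BRENDA) plays for a
#' real screen.
#'
#' @param path Path to the TSV file.
#' @param cofactor_blacklist Compound ids excluded from ligand inference;
#'   default [default_cofactor_blacklist()].
#' @return Object of class `reaction_kb`: list with `entries` (data.frame
#'   with list columns `substrates`, `products`) and `cofactor_blacklist`.
#' @export
load_reaction_kb <- function(path,
                             cofactor_blacklist = default_cofactor_blacklist()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("ec", "substrates", "products", "reversible")
  if (!all(needed %in% names(raw))) {
    stop("reaction KB must have columns: ", paste(needed, collapse = ", "))
  }
  split_cpds <- function(x) {
    out <- trimws(tolower(strsplit(x, ";", fixed = TRUE)[[1]]))
    unique(out[nzchar(out)])
  }
  entries <- data.frame(ec = trimws(raw$ec),
                        reversible = tolower(trimws(raw$reversible)) %in%
                          c("true", "t", "1", "yes"),
                        stringsAsFactors = FALSE)
  entries$substrates <- lapply(raw$substrates, split_cpds)
  entries$products <- lapply(raw$products, split_cpds)
  for (i in seq_len(nrow(entries))) {
    if (!length(entries$substrates[[i]]) || !length(entries$products[[i]])) {
      stop("reaction KB line ", i + 1L,
           ": substrates and products must both be non-empty")
    }
    if (length(intersect(entries$substrates[[i]], entries$products[[i]]))) {
      stop("reaction KB line ", i + 1L,
           ": substrates and products overlap")
    }
  }
  key <- paste(entries$ec,
               vapply(entries$substrates, paste, "", collapse = ";"),
               vapply(entries$products, paste, "", collapse = ";"))
  if (anyDuplicated(key)) {
    warning("duplicate reaction rows deduplicated")
    entries <- entries[!duplicated(key), , drop = FALSE]
  }
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 cofactor_blacklist = tolower(cofactor_blacklist)),
            class = "reaction_kb")
}

#' Write a reaction knowledgebase to TSV
#'
#' @param kb `reaction_kb` object.
#' @param path Output path.
#' @export
write_reaction_kb <- function(kb, path) {
  tab <- data.frame(
    ec = kb$entries$ec,
    substrates = vapply(kb$entries$substrates, paste, "", collapse = ";"),
    products = vapply(kb$entries$products, paste, "", collapse = ";"),
    reversible = ifelse(kb$entries$reversible, "true", "false"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Reactions encoded by an operon
#'
#' Union (set semantics: each distinct reaction once) of knowledgebase
#' entries over the EC numbers carried by the operon's member genes. An
#' unknown EC yields an explicit empty result, never a silent failure.
#'
#' @param operon One row of the [infer_operons()] table.
#' @param annotation The `genome_annotation` holding the member genes.
#' @param kb `reaction_kb` from [load_reaction_kb()].
#' @return data.frame of reaction entries (possibly 0 rows).
#' @export
operon_reaction_set <- function(operon, annotation, kb) {
  gene_ids <- operon$genes[[1]]
  genes <- annotation$genes[annotation$genes$gene_id %in% gene_ids, ,
                            drop = FALSE]
  ecs <- unique(unlist(genes$ec_numbers))
  if (!length(ecs)) {
    message("operon ", operon$operon_id, ": no EC numbers on member genes")
    return(kb$entries[integer(), , drop = FALSE])
  }
  missing <- setdiff(ecs, kb$entries$ec)
  if (length(missing)) {
    message("operon ", operon$operon_id, ": EC number(s) not in KB: ",
            paste(missing, collapse = ", "))
  }
  kb$entries[kb$entries$ec %in% ecs, , drop = FALSE]
}

#' Infer the primary substrate of an operon-encoded pathway
#'
#' Formalises "compare the substrates and products of each enzyme and
#' conclude the primary substrate" as graph-source inference: reactions (with
#' blacklisted cofactors removed; reversible reactions counted in both
#' directions) define a directed compound graph, candidates are compounds
#' consumed by at least one reaction, and the primary substrate is a graph
#' source — consumed but never produced. Ranking is by `produced_by`
#' ascending, then `consumed_by` descending, then compound id.
#'
#' @param reactions data.frame of reaction entries
#'   (see [operon_reaction_set()]).
#' @param kb `reaction_kb` providing the cofactor blacklist.
#' @return data.frame of ranked candidates (`compound`, `consumed_by`,
#'   `produced_by`, `rank`) with attribute `ambiguous = TRUE` when every
#'   consumed compound is also produced (cyclic pathway, no source).
#'   Zero rows when no reaction survives cofactor removal.
#' @export
infer_primary_substrate <- function(reactions, kb) {
  empty <- data.frame(compound = character(), consumed_by = integer(),
                      produced_by = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(reactions) || nrow(reactions) == 0L) return(empty)
  black <- kb$cofactor_blacklist
  consumed <- list()
  produced <- list()
  for (i in seq_len(nrow(reactions))) {
    subs <- setdiff(reactions$substrates[[i]], black)
    prods <- setdiff(reactions$products[[i]], black)
    consumed[[length(consumed) + 1L]] <- subs
    produced[[length(produced) + 1L]] <- prods
    if (isTRUE(reactions$reversible[i])) {
      consumed[[length(consumed) + 1L]] <- prods
      produced[[length(produced) + 1L]] <- subs
    }
  }
  cons_counts <- table(unlist(consumed))
  prod_counts <- table(unlist(produced))
  cand <- names(cons_counts)
  if (!length(cand)) return(empty)
  res <- data.frame(
    compound = cand,
    consumed_by = as.integer(cons_counts[cand]),
    produced_by = as.integer(ifelse(is.na(prod_counts[cand]), 0L,
                                    prod_counts[cand])),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$produced_by, -res$consumed_by, res$compound), ,
             drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "ambiguous") <- all(res$produced_by > 0L)
  res
}

#' Assemble and classify candidate inducible systems
#'
#' Applies the minimum-catalytic-genes rule to the divergent pairs, runs
#' ligand inference on the survivors, and classifies each pair as
#' `proposed` (ranked ligand list available), `no_ligand` (operon ECs absent
#' from the knowledgebase or only cofactors involved) or `filtered_out`
#' (fewer than `min_catalytic` catalytic genes).
#'
#' @param pairs data.frame from [find_divergent_candidates()].
#' @param annotation The source `genome_annotation`.
#' @param operons Operon table from [infer_operons()].
#' @param kb `reaction_kb`.
#' @param min_catalytic Minimum catalytic genes in the operon; default 2.
#' @return data.frame of candidates sorted by replicon and promoter start,
#'   with `status`, `reason` and a `ligands` list column of ranked candidate
#'   tables.
#' @export
assemble_candidates <- function(pairs, annotation, operons, kb,
                                min_catalytic = 2) {
  n <- nrow(pairs)
  status <- character(n)
  reason <- character(n)
  ligands <- vector("list", n)
  for (i in seq_len(n)) {
    if (pairs$n_catalytic[i] < min_catalytic) {
      status[i] <- "filtered_out"
      reason[i] <- "min_catalytic"
      ligands[[i]] <- infer_primary_substrate(NULL, kb)
      next
    }
    op <- operons[operons$operon_id == pairs$operon_id[i], , drop = FALSE]
    reactions <- suppressMessages(operon_reaction_set(op, annotation, kb))
    lg <- infer_primary_substrate(reactions, kb)
    if (nrow(lg) == 0L) {
      status[i] <- "no_ligand"
      reason[i] <- "no reactions found for operon EC numbers"
    } else {
      status[i] <- "proposed"
      reason[i] <- if (isTRUE(attr(lg, "ambiguous"))) {
        "ambiguous: no graph source (cyclic reaction set)"
      } else ""
    }
    ligands[[i]] <- lg
  }
  res <- pairs
  res$status <- status
  res$reason <- reason
  res$ligands <- ligands
  res <- res[order(res$replicon_id, res$promoter_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
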