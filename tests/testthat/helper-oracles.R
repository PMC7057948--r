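# Independent oracles and small fixture builders used across the suite.

# Brute-force graph-source enumeration, independent of the package's
# ranking implementation: a source is consumed by >= 1 reaction and
# produced by none (reversible reactions count both ways).
oracle_graph_sources <- function(reactions, blacklist = character()) {
  consumed <- character()
  produced <- character()
  for (i in seq_len(nrow(reactions))) {
    subs <- setdiff(reactions$substrates[[i]], blacklist)
    prods <- setdiff(reactions$products[[i]], blacklist)
    consumed <- c(consumed, subs)
    produced <- c(produced, prods)
    if (isTRUE(reactions$reversible[i])) {
      consumed <- c(consumed, prods)
      produced <- c(produced, subs)
    }
  }
  sort(setdiff(unique(consumed), unique(produced)))
}

# Reaction table (list-column form) from triples, for direct calls to
# infer_primary_substrate().
reaction_table <- function(...) {
  rx <- list(...)
  df <- data.frame(ec = vapply(rx, `[[`, "", "ec"),
                   reversible = vapply(rx, function(r) {
                     isTRUE(r$reversible)
                   }, logical(1)),
                   stringsAsFactors = FALSE)
  df$substrates <- lapply(rx, `[[`, "substrates")
  df$products <- lapply(rx, `[[`, "products")
  df
}

toy_kb <- function(blacklist = character()) {
  structure(list(entries = NULL, cofactor_blacklist = blacklist),
            class = "reaction_kb")
}

# Random acyclic reaction set over compounds c01..cNN: every reaction maps
# lower-index compounds to strictly higher-index ones, so the graph is a DAG
# by construction.
random_acyclic_reactions <- function(n_compounds, n_reactions) {
  cpds <- sprintf("c%02d", seq_len(n_compounds))
  rx <- vector("list", n_reactions)
  for (i in seq_len(n_reactions)) {
    cut <- sample(2:(n_compounds - 1), 1)
    subs <- sample(cpds[1:(cut - 1)], min(sample(1:2, 1), cut - 1))
    prods <- sample(cpds[cut:n_compounds],
                    min(sample(1:2, 1), n_compounds - cut + 1))
    rx[[i]] <- list(ec = sprintf("1.1.1.%d", i), substrates = subs,
                    products = prods, reversible = FALSE)
  }
  do.call(reaction_table, rx)
}

# Exhaustive coarse grid search oracle for the Hill fit: over (K_m, h) the
# model is linear in (b_max, b_min), solved in closed form at each node.
oracle_grid_sse <- function(I, RFP, n_km = 80, n_h = 60) {
  nz <- I[I > 0]
  km_grid <- exp(seq(log(min(nz) / 10), log(max(nz) * 10),
                     length.out = n_km))
  h_grid <- seq(0.1, 10, length.out = n_h)
  best <- Inf
  for (km in km_grid) {
    for (h in h_grid) {
      f <- ifelse(I > 0, I^h / (km^h + I^h), 0)
      X <- cbind(f, 1)
      beta <- tryCatch(qr.solve(X, RFP), error = function(e) NULL)
      if (is.null(beta)) next
      sse <- sum((RFP - X %*% beta)^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# Noise-free dose-response dataset straight from the Hill model, bypassing
# the plate simulator.
hill_dataset <- function(b_min, b_max, K_m, h,
                         concentrations = K_m * 10^seq(-2, 2,
                                                       length.out = 12),
                         n_uninduced = 3) {
  I <- c(rep(0, n_uninduced), concentrations)
  RFP <- hill_model(I, b_max, K_m, h, b_min)
  dose_response_dataset(data.frame(concentration_M = I, norm_fl = RFP))
}

# Hand-authored GenBank fixture: 3 CDS (one minus strand, one with an EC
# qualifier, one with EC in product text) plus a short sequence.
write_fixture_genbank <- function(path) {
  writeLines(c(
    "LOCUS       FIXREP 600 bp    DNA     linear BCT 01-JAN-2000",
    "DEFINITION  hand-written parser fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "                     /organism=\"synthetic construct\"",
    "     CDS             11..100",
    "                     /locus_tag=\"GENE_A\"",
    "                     /product=\"alpha enzyme\"",
    "                     /EC_number=\"4.1.1.11\"",
    "     CDS             complement(151..300)",
    "                     /locus_tag=\"GENE_B\"",
    "                     /product=\"beta regulator\"",
    "     CDS             351..500",
    "                     /locus_tag=\"GENE_C\"",
    "                     /product=\"gamma dehydrogenase (EC 1.2.3.4)\"",
    "ORIGIN",
    vapply(seq(1, 600, 60), function(i) {
      sprintf("%9d %s", i, paste(rep("acgtacgtac", 6), collapse = " "))
    }, character(1)),
    "//"
  ), path)
}
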