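#' Specification for a synthetic genome with planted inducible systems
#'
#' Describes how many divergent TR-operon systems to plant, how many decoy
#' arrangements to scatter between them, and the geometry ranges. Decoys
#' cycle through three classes that the screen must reject: convergent
#' TR/operon pairs (3' ends facing), co-directional TR/operon pairs, and
#' divergent TRs opposing a single-gene operon (caught by the
#' minimum-catalytic-genes rule).
#'
#' @param n_systems Number of planted true systems.
#' @param n_decoys Number of decoy arrangements.
#' @param intergenic_range Range (bp) for planted promoter lengths;
#'   default 80-300 (compact divergent promoters; the screen default caps
#'   at 500).
#' @param operon_size_range Genes per planted operon; default 2-4.
#' @param gene_len_range CDS length range in bp.
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   outputs.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(n_systems = 3, n_decoys = 4,
                       intergenic_range = c(80, 300),
                       operon_size_range = c(2, 4),
                       gene_len_range = c(300, 900),
                       seed = 1) {
  stopifnot(n_systems >= 0, n_decoys >= 0,
            intergenic_range[1] <= intergenic_range[2],
            operon_size_range[1] >= 1,
            operon_size_range[1] <= operon_size_range[2])
  structure(list(n_systems = n_systems, n_decoys = n_decoys,
                 intergenic_range = intergenic_range,
                 operon_size_range = operon_size_range,
                 gene_len_range = gene_len_range, seed = seed),
            class = "plant_spec")
}

#' Generate a synthetic annotated genome with planted inducible systems
#'
#' Writes a single-replicon GenBank flat file containing, per planted
#' system, a family-labelled TR CDS divergently opposed to an operon of
#' EC-annotated CDS whose EC numbers form a linear pathway in the companion
#' toy reaction knowledgebase (entry compound -> intermediates -> end
#' product), plus the requested decoys. A JSON manifest records the ground
#' truth: each planted system's TR id, promoter interval and true entry
#' compound.
#'
#' Layout elements are separated by spacers longer than both the operon
#' `max_gap` and the screen's `max_intergenic` defaults so that planted
#' arrangements never merge with neighbours.
#'
#' @param spec `plant_spec` object.
#' @param out_dir Directory to write `genome.gbk`, `reaction_kb.tsv` and
#'   `manifest.json` into (created if needed).
#' @return Invisibly, a list with the three file paths and the manifest.
#' @export
generate_toy_genome <- function(spec, out_dir) {
  stopifnot(inherits(spec, "plant_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, generate_toy_genome_impl(spec, out_dir))
}

generate_toy_genome_impl <- function(spec, out_dir) {
  families <- c("LysR", "MarR", "MocR", "AsnC", "IclR", "TetR", "GntR")
  spacer <- 800L  # > max_gap and > max_intergenic defaults
  pos <- 200L
  features <- list()
  kb_rows <- list()
  manifest_systems <- list()
  ec_counter <- 0L

  rint <- function(lo, hi) as.integer(floor(stats::runif(1, lo, hi + 1)))

  add_cds <- function(start, len, strand, gene_id, product, ec = NULL) {
    features[[length(features) + 1L]] <<- list(
      start = start, end = start + len, strand = strand,
      gene_id = gene_id, product = product, ec = ec)
    start + len
  }

  # planted true systems: minus-strand TR, gap, plus-strand operon with a
  # linear EC pathway
  for (s in seq_len(spec$n_systems)) {
    fam <- families[(s - 1L) %% length(families) + 1L]
    tr_len <- rint(spec$gene_len_range[1], spec$gene_len_range[2])
    tr_id <- sprintf("SYS%02d_TR", s)
    tr_start <- pos
    pos <- add_cds(tr_start, tr_len, "-", tr_id,
                   paste(fam, "family transcriptional regulator"))
    gap <- rint(spec$intergenic_range[1], spec$intergenic_range[2])
    promoter <- c(pos, pos + gap)
    pos <- pos + gap
    n_op <- rint(spec$operon_size_range[1], spec$operon_size_range[2])
    entry <- sprintf("cpd_s%02d_0", s)
    for (g in seq_len(n_op)) {
      ec_counter <- ec_counter + 1L
      ec <- sprintf("9.9.%d.%d", s, g)
      sub_cpd <- sprintf("cpd_s%02d_%d", s, g - 1L)
      prod_cpd <- sprintf("cpd_s%02d_%d", s, g)
      kb_rows[[length(kb_rows) + 1L]] <- data.frame(
        ec = ec, substrates = sub_cpd, products = prod_cpd,
        reversible = "false", stringsAsFactors = FALSE)
      glen <- rint(spec$gene_len_range[1], spec$gene_len_range[2])
      pos <- add_cds(pos, glen, "+", sprintf("SYS%02d_G%d", s, g),
                     sprintf("pathway enzyme %d dehydrogenase", g), ec)
      if (g < n_op) pos <- pos + rint(20, 120)  # within-operon gap <= 150
    }
    manifest_systems[[length(manifest_systems) + 1L]] <- list(
      tr_gene_id = tr_id, tr_family = fam,
      promoter_start = promoter[1], promoter_end = promoter[2],
      entry_compound = entry, n_operon_genes = n_op)
    pos <- pos + spacer
  }

  # decoys cycle through the three rejected classes
  for (d in seq_len(spec$n_decoys)) {
    kind <- c("convergent", "codirectional", "single_gene")[
      (d - 1L) %% 3L + 1L]
    fam <- families[(d - 1L) %% length(families) + 1L]
    tr_len <- rint(spec$gene_len_range[1], spec$gene_len_range[2])
    glen <- rint(spec$gene_len_range[1], spec$gene_len_range[2])
    gap <- rint(spec$intergenic_range[1], spec$intergenic_range[2])
    id <- sprintf("DEC%02d", d)
    if (kind == "convergent") {
      # plus-strand TR then minus-strand operon: 3' ends face each other
      pos <- add_cds(pos, tr_len, "+", paste0(id, "_TR"),
                     paste(fam, "family transcriptional regulator"))
      pos <- pos + gap
      ec_counter <- ec_counter + 1L
      ec1 <- sprintf("8.8.%d.1", d); ec2 <- sprintf("8.8.%d.2", d)
      kb_rows[[length(kb_rows) + 1L]] <- data.frame(
        ec = ec1, substrates = sprintf("cpd_d%02d_0", d),
        products = sprintf("cpd_d%02d_1", d), reversible = "false",
        stringsAsFactors = FALSE)
      kb_rows[[length(kb_rows) + 1L]] <- data.frame(
        ec = ec2, substrates = sprintf("cpd_d%02d_1", d),
        products = sprintf("cpd_d%02d_2", d), reversible = "false",
        stringsAsFactors = FALSE)
      pos <- add_cds(pos, glen, "-", paste0(id, "_G1"),
                     "decoy enzyme transferase", ec1)
      pos <- pos + rint(20, 120)
      pos <- add_cds(pos, glen, "-", paste0(id, "_G2"),
                     "decoy enzyme hydrolase", ec2)
    } else if (kind == "codirectional") {
      pos <- add_cds(pos, tr_len, "+", paste0(id, "_TR"),
                     paste(fam, "family transcriptional regulator"))
      pos <- pos + gap + 200L  # > max_gap so the TR is not absorbed
      pos <- add_cds(pos, glen, "+", paste0(id, "_G1"),
                     "decoy enzyme kinase")
      pos <- pos + rint(20, 120)
      pos <- add_cds(pos, glen, "+", paste0(id, "_G2"),
                     "decoy enzyme lyase")
    } else {
      # divergent but single-gene operon: fails the >=2-catalytic rule
      pos <- add_cds(pos, tr_len, "-", paste0(id, "_TR"),
                     paste(fam, "family transcriptional regulator"))
      pos <- pos + gap
      pos <- add_cds(pos, glen, "+", paste0(id, "_G1"),
                     "lone decoy enzyme decarboxylase")
    }
    pos <- pos + spacer
  }

  genome_len <- pos + 200L
  seq <- paste(c("A", "C", "G", "T")[
    as.integer(floor(stats::runif(genome_len, 1, 5)))], collapse = "")

  gbk_path <- file.path(out_dir, "genome.gbk")
  kb_path <- file.path(out_dir, "reaction_kb.tsv")
  manifest_path <- file.path(out_dir, "manifest.json")

  write_genbank(gbk_path, "TOY_REPLICON", seq, features)
  kb_tab <- if (length(kb_rows)) do.call(rbind, kb_rows) else
    data.frame(ec = "9.9.999.1", substrates = "cpd_dummy_a",
               products = "cpd_dummy_b", reversible = "false",
               stringsAsFactors = FALSE)
  utils::write.table(kb_tab, kb_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(seed = spec$seed, n_systems = spec$n_systems,
                   n_decoys = spec$n_decoys, systems = manifest_systems)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(genome = gbk_path, kb = kb_path, manifest_path = manifest_path,
                 manifest = manifest))
}

# Run `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Minimal GenBank flat-file writer (LOCUS, FEATURES, ORIGIN).
# Coordinates in `features` are 0-based half-open; written 1-based inclusive.
write_genbank <- function(path, locus, sequence, features) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nchar(sequence)
  writeLines(sprintf(
    "LOCUS       %s %d bp    DNA     circular BCT 01-JAN-2000", locus, n),
    con)
  writeLines(sprintf("DEFINITION  synthetic toy genome %s.", locus), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  writeLines(sprintf("                     /organism=\"synthetic construct\""),
             con)
  for (f in features) {
    loc <- sprintf("%d..%d", f$start + 1L, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", f$gene_id),
               con)
    writeLines(sprintf("                     /product=\"%s\"", f$product),
               con)
    if (!is.null(f$ec)) {
      writeLines(sprintf("                     /EC_number=\"%s\"", f$ec), con)
    }
  }
  writeLines("ORIGIN", con)
  i <- 1L
  while (i <= n) {
    chunk_end <- min(i + 59L, n)
    chunk <- substr(sequence, i, chunk_end)
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, tolower(paste(groups, collapse = " "))),
               con)
    i <- i + 60L
  }
  writeLines("//", con)
}

#' Specification for a simulated plate-reader experiment
#'
#' @param b_min,b_max,K_m,h True Hill parameters (AFU/OD, AFU/OD, molar,
#'   dimensionless).
#' @param concentrations Inducer concentrations (molar); 0 is added
#'   automatically for the uninduced wells.
#' @param noise_cv Multiplicative coefficient of variation on fluorescence;
#'   0 for noise-free data.
#' @param n_replicates Wells per concentration.
#' @param od0,od_max,growth_rate Logistic growth parameters (initial OD,
#'   carrying capacity, per-minute rate). Defaults mirror the dose-response
#'   acquisition protocol: exponentially growing cells at OD600 0.2 diluted
#'   142.5/150 into the well (od0 = 0.19), with a roughly 2-h doubling time
#'   typical of minimal-medium growth.
#' @param blank_fl,blank_od Medium autofluorescence and absorbance.
#' @param sampling_interval,duration Acquisition grid in minutes
#'   (defaults: every 5 min over 6 h).
#' @param n_blanks Medium-only wells.
#' @param seed Integer seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(b_min = 100, b_max = 800, K_m = 201e-6, h = 0.75,
                     concentrations = K_m * 10^seq(-2, 2, length.out = 12),
                     noise_cv = 0, n_replicates = 3,
                     od0 = 0.19, od_max = 1.5, growth_rate = 0.005,
                     blank_fl = 50, blank_od = 0.04,
                     sampling_interval = 5, duration = 360,
                     n_blanks = 3, seed = 1) {
  stopifnot(noise_cv >= 0, n_replicates >= 1, all(concentrations > 0))
  structure(as.list(environment()), class = "sim_spec")
}

#' Simulate plate-reader time courses for one inducible system
#'
#' OD follows logistic growth (inducer-independent); the true normalised
#' fluorescence at any time equals the Hill response at that well's inducer
#' concentration (expression is treated as at steady state on the
#' normalised scale, so inverting the normalisation recovers the Hill
#' parameters exactly in the noise-free limit). Raw fluorescence is
#' reconstructed as `truth * OD + blank autofluorescence` and then
#' perturbed by multiplicative log-normal noise of the stated CV. Blank
#' wells carry the medium signals alone.
#'
#' @param spec `sim_spec` object.
#' @param system_id Label written into the `system` column.
#' @return Long-format data.frame with columns `well`, `system`, `inducer`,
#'   `concentration_M`, `time_min`, `fluorescence`, `od600`, `is_blank` —
#'   the format [normalize_measurements()] consumes.
#' @export
simulate_plate_timecourse <- function(spec, system_id = "sim") {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, simulate_plate_timecourse_impl(spec, system_id))
}

simulate_plate_timecourse_impl <- function(spec, system_id) {
  times <- seq(0, spec$duration, by = spec$sampling_interval)
  conc <- c(0, spec$concentrations)
  # logistic growth shared by all wells
  od <- spec$od_max / (1 + (spec$od_max / spec$od0 - 1) *
                         exp(-spec$growth_rate * times))
  rows <- list()
  # log-normal with unit mean: sigma of log from the CV
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  for (ci in seq_along(conc)) {
    truth <- hill_model(conc[ci], spec$b_max, spec$K_m, spec$h, spec$b_min)
    for (r in seq_len(spec$n_replicates)) {
      fl_true <- truth * od + spec$blank_fl
      noise <- if (spec$noise_cv > 0) {
        exp(stats::rnorm(length(times), -sdlog^2 / 2, sdlog))
      } else {
        rep(1, length(times))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        well = sprintf("c%02d_r%d", ci - 1L, r),
        system = system_id,
        inducer = if (conc[ci] > 0) "effector" else "none",
        concentration_M = conc[ci],
        time_min = times,
        fluorescence = fl_true * noise,
        od600 = od + spec$blank_od,
        is_blank = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  for (b in seq_len(spec$n_blanks)) {
    rows[[length(rows) + 1L]] <- data.frame(
      well = sprintf("blank_%d", b),
      system = system_id, inducer = "none", concentration_M = 0,
      time_min = times,
      fluorescence = spec$blank_fl, od600 = spec$blank_od,
      is_blank = TRUE, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Run the full dose-response recovery pipeline on simulated data
#'
#' Convenience composition: simulate -> normalise -> window -> fit. In the
#' noise-free limit this composition is the identity on the Hill
#' parameters.
#'
#' @param spec `sim_spec`.
#' @param t_window Induction window in minutes; default 80.
#' @return `hill_fit` object.
#' @export
recover_hill_from_simulation <- function(spec, t_window = 80) {
  courses <- simulate_plate_timecourse(spec)
  norm <- normalize_measurements(courses)
  win <- extract_induction_window(norm, t_window = t_window)
  fit_hill(dose_response_dataset(win))
}
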