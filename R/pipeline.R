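# Orchestration: validated configuration and end-to-end design runs.

CONFIG_KEYS <- c("genome", "gff3", "vcf", "genes", "cassette", "design_type",
                 "sic", "lha_len", "rha_len", "min_splice_distance",
                 "variant_pad", "any_isoform", "validation", "out_dir",
                 "seed")

#' Build and validate a design configuration
#'
#' @param genome path to the reference FASTA (or a loaded genome).
#' @param gff3 path to the GFF3 annotation (or a GRanges).
#' @param genes character vector of gene ids to design for.
#' @param cassette cassette name from [cassette_library()] (or a
#'   `cassette_template`).
#' @param design_type "ssdna" (long-primer PCR donor), "synthesis" (direct
#'   dsDNA drop-in synthesis plasmid) or "int100" (stuffer synthesis plus
#'   directional subcloning of `sic`).
#' @param vcf optional strain-variant VCF path.
#' @param sic cassette name (or template) subcloned in int100 designs.
#' @param lha_len,rha_len homology-arm lengths (default 100/100).
#' @param min_splice_distance guide cut-to-junction buffer, nt (default 50).
#' @param variant_pad padding for variant overlap flags, nt (default 0).
#' @param any_isoform also target introns not shared by all coding
#'   transcripts (default FALSE).
#' @param validation parameter list from [validation_params()].
#' @param out_dir output directory (NULL: no files written).
#' @param seed integer seed recorded in the run summary.
#' @return validated `design_config` list.
#' @export
design_config <- function(genome, gff3, genes, cassette,
                          design_type = c("ssdna", "synthesis", "int100"),
                          vcf = NULL,
                          sic = "attP-FRT-SA-T2A-GAL4-polyA-3XP3-EGFP-FRT-attP",
                          lha_len = 100L, rha_len = 100L,
                          min_splice_distance = 50L, variant_pad = 0L,
                          any_isoform = FALSE,
                          validation = validation_params(),
                          out_dir = NULL, seed = 1L) {
  design_type <- match.arg(design_type)
  cfg <- list(genome = genome, gff3 = gff3, vcf = vcf, genes = genes,
              cassette = cassette, design_type = design_type, sic = sic,
              lha_len = as.integer(lha_len), rha_len = as.integer(rha_len),
              min_splice_distance = as.integer(min_splice_distance),
              variant_pad = as.integer(variant_pad),
              any_isoform = isTRUE(any_isoform), validation = validation,
              out_dir = out_dir, seed = as.integer(seed))
  structure(cfg, class = "design_config")
}

#' Read a design configuration from a YAML file
#'
#' Unknown keys are rejected.
#'
#' @param path YAML file with [design_config()] fields.
#' @return `design_config`.
#' @export
read_design_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown)) {
    dropin_error(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")),
                 "dropin_config_error")
  }
  if (!is.null(raw$validation)) raw$validation <-
    do.call(validation_params, raw$validation)
  do.call(design_config, raw)
}

resolve_template <- function(x) {
  if (inherits(x, "cassette_template")) return(x)
  lib <- cassette_library()
  if (is.character(x) && x %in% names(lib)) return(lib[[x]])
  dropin_error(sprintf("unknown cassette '%s'; available: %s", x,
                       paste(names(lib), collapse = ", ")),
               "dropin_config_error")
}

#' Run the full drop-in design pipeline
#'
#' Per requested gene: pick a coding intron (by default one shared by all
#' coding transcripts), enumerate/filter/rank guides, extract homology
#' arms, assemble the requested donor class, simulate the HDR-edited allele
#' and its trap transcript, and design in/out validation PCR. Per-gene
#' failures are isolated and reported; every exclusion decision is logged
#' in the summary. With `out_dir` set, writes per gene: guide report TSV,
#' ordering sheet TSV, donor and edited-allele GenBank records, validation
#' primer TSV, and a run-level JSON summary.
#'
#' @param config a `design_config` (or path to a YAML config).
#' @return (invisibly) list `summary` (per-gene results), `n_failed`,
#'   `designs` (per-gene design objects for successful genes).
#' @export
run_design <- function(config) {
  if (is.character(config)) config <- read_design_config(config)
  stopifnot(inherits(config, "design_config"))
  set.seed(config$seed)
  genome <- if (is.character(config$genome)) load_genome(config$genome)
    else config$genome
  models <- gene_models(config$gff3, gene_ids = config$genes)
  missing <- setdiff(config$genes, names(models))
  variants <- if (!is.null(config$vcf)) {
    if (is.character(config$vcf)) load_variants(config$vcf, genome)
    else config$vcf
  } else NULL
  template <- resolve_template(config$cassette)
  sic <- if (config$design_type == "int100") resolve_template(config$sic)
    else NULL
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  summary <- list()
  designs <- list()
  for (gid in config$genes) {
    if (gid %in% missing) {
      summary[[gid]] <- list(gene_id = gid, status = "failed",
                             reason = "gene not found in annotation")
      next
    }
    res <- tryCatch(
      design_gene(genome, models[[gid]], variants, template, sic, config,
                  out_dir),
      dropin_error = function(e) list(
        gene_id = gid, status = "failed", reason = conditionMessage(e),
        exclusions = e$exclusions %||% NULL)
    )
    if (identical(res$status, "failed")) {
      summary[[gid]] <- res
    } else {
      summary[[gid]] <- res$summary
      designs[[gid]] <- res$design
    }
  }
  n_failed <- sum(vapply(summary, function(s)
    identical(s$status, "failed"), logical(1)))
  run <- list(seed = config$seed, design_type = config$design_type,
              cassette = template$name, genes = summary,
              n_failed = n_failed)
  if (!is.null(out_dir)) {
    jsonlite::write_json(run, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(summary = run, n_failed = n_failed, designs = designs))
}

# design one gene; raises dropin_error subclasses on failure
design_gene <- function(genome, gene, variants, template, sic, cfg, out_dir) {
  introns <- find_coding_introns(gene)
  if (!cfg$any_isoform) {
    introns <- introns[introns$shared_by_all_coding_transcripts, , drop = FALSE]
  }
  if (nrow(introns) == 0L) {
    dropin_error(sprintf("gene '%s': no eligible coding intron", gene$gene_id),
                 "dropin_no_intron_error")
  }
  gvars <- if (!is.null(variants)) {
    variants[variants$contig == gene$contig, , drop = FALSE]
  } else NULL
  synth <- cfg$design_type %in% c("synthesis", "int100")
  grna1 <- if (synth) grna1_unit() else NULL
  log <- list()
  for (ii in seq_len(nrow(introns))) {
    intron <- introns[ii, , drop = FALSE]
    guides <- scan_guides(genome, gene$contig, intron$start, intron$end)
    guides <- filter_by_variants(guides, gvars, pad = cfg$variant_pad)
    ranked <- tryCatch(
      rank_guides(guides, intron, genome = genome,
                  min_splice_distance = cfg$min_splice_distance,
                  lha_len = cfg$lha_len, rha_len = cfg$rha_len,
                  forbidden_sites = if (synth) grna1$unit else character(0)),
      dropin_no_viable_guide = function(e) {
        log[[length(log) + 1L]] <<- list(
          intron = ii, event = "no_viable_guide",
          detail = conditionMessage(e))
        NULL
      })
    if (is.null(ranked)) next
    for (gi in seq_len(nrow(ranked))) {
      guide <- ranked[gi, , drop = FALSE]
      arms <- tryCatch(
        design_arms(genome, gene$contig, guide$cut_site,
                    gene_strand = gene$strand,
                    lha_len = cfg$lha_len, rha_len = cfg$rha_len,
                    grna1_site = if (synth) grna1$unit else NULL,
                    variants = gvars),
        dropin_error = function(e) {
          log[[length(log) + 1L]] <<- list(
            intron = ii, guide = guide$protospacer, event = "arm_rejected",
            detail = conditionMessage(e))
          NULL
        })
      if (is.null(arms)) next
      if (arms$flags$contains_gRNA1_site) {
        log[[length(log) + 1L]] <- list(
          intron = ii, guide = guide$protospacer, event = "arm_rejected",
          detail = "gRNA1 unit present in a homology arm")
        next
      }
      built <- tryCatch(
        build_donor(genome, gene, intron, guide, arms, template, sic, cfg),
        dropin_error = function(e) {
          log[[length(log) + 1L]] <<- list(
            intron = ii, guide = guide$protospacer, event = "donor_rejected",
            detail = conditionMessage(e))
          NULL
        })
      if (is.null(built)) next
      built$log <- log
      return(finalize_gene(built, gene, out_dir))
    }
  }
  dropin_error(sprintf(
    "gene '%s': design failed in every eligible intron (%d exclusions logged)",
    gene$gene_id, length(log)), "dropin_gene_failed", exclusions = log)
}

build_donor <- function(genome, gene, intron, guide, arms, template, sic, cfg) {
  has_sa <- !is.null(feature_interval(template, "SA"))
  tmpl <- if (has_sa) cassette_phase_variant(template, intron$phase)
    else template
  out <- list(gene_id = gene$gene_id, intron = intron, guide = guide,
              arms = arms, template = tmpl, design_type = cfg$design_type,
              validation_params = cfg$validation)
  if (cfg$design_type == "ssdna") {
    out$ssdna <- build_ssdna_design(arms, tmpl)
    payload <- tmpl$core_seq
    out$donor_len <- out$ssdna$donor$total_len
  } else if (cfg$design_type == "synthesis") {
    out$construct <- build_synthesis_construct(arms, genome, payload = tmpl)
    payload <- out$construct$payload_seq
    out$donor_len <- out$construct$lengths$cassette_plus_arms
  } else {
    stuffer <- build_synthesis_construct(arms, genome, payload_mode = "stuffer",
                                         sic_core = sic$core_seq)
    out$construct <- stuffer
    out$plasmid <- simulate_subcloning(stuffer, sic$core_seq)
    payload <- paste0(stuffer$re1$site, sic$core_seq, stuffer$re2$site)
    out$donor_len <- nchar(arms$lha) + nchar(payload) + nchar(arms$rha)
    # for int100 the molecular consequence is that of the subcloned SIC
    tmpl <- if (!is.null(feature_interval(sic, "SA")))
      cassette_phase_variant(sic, intron$phase) else sic
    out$template <- tmpl
    has_sa <- !is.null(feature_interval(tmpl, "SA"))
  }
  insert_core <- if (cfg$design_type == "int100") payload else tmpl$core_seq
  out$edited <- simulate_hdr(genome, arms, insert_core, guide = guide)
  if (out$edited$recut_sites > 0L) {
    dropin_error("edited allele retains an intact guide target site",
                 "dropin_hdr_error")
  }
  out$classification <- classify_allele(tmpl, "intron")
  if (has_sa) {
    out$trap_report <- predict_trap_transcript(out$edited, gene, genome, tmpl)
  }
  out$validation <- design_validation_primers(out$edited, cfg$validation)
  out
}

finalize_gene <- function(built, gene, out_dir) {
  paths <- NULL
  rel_paths <- NULL
  if (!is.null(out_dir)) {
    gdir <- file.path(out_dir, built$gene_id)
    if (!dir.exists(gdir)) dir.create(gdir, recursive = TRUE)
    # the summary records out_dir-relative paths so reruns are byte-identical
    rel_paths <- list(
      guides = file.path(built$gene_id, "guides.tsv"),
      ordering = file.path(built$gene_id, "ordering_sheet.tsv"),
      donor = file.path(built$gene_id, "donor.gb"),
      edited = file.path(built$gene_id, "edited_allele.gb"),
      primers = file.path(built$gene_id, "validation_primers.tsv"))
    paths <- lapply(rel_paths, function(p) file.path(out_dir, p))
    write_guide_report(built$guide, paths$guides, gene_id = built$gene_id,
                       intron_index = built$intron$start)
    design_obj <- built$ssdna %||% built$construct
    write.table(ordering_sheet(design_obj, built$gene_id), paths$ordering,
                sep = "\t", quote = FALSE, row.names = FALSE)
    donor_seq <- if (!is.null(built$ssdna)) built$ssdna$donor$duplex_top
      else if (!is.null(built$plasmid)) built$plasmid$seq
      else built$construct$plasmid$seq
    write_genbank(donor_seq, paths$donor,
                  name = paste0(built$gene_id, "_donor"),
                  circular = is.null(built$ssdna))
    ins <- built$edited$insert_interval
    write_genbank(built$edited$sequence, paths$edited,
                  name = paste0(built$gene_id, "_edited"),
                  features = data.frame(label = "drop-in insert",
                                        start = ins["start"], end = ins["end"]))
    write_primer_report(built$validation, paths$primers)
  }
  summary <- list(
    gene_id = built$gene_id,
    status = "ok",
    intron = list(start = built$intron$start, end = built$intron$end,
                  phase = built$intron$phase),
    guide = list(protospacer = built$guide$protospacer,
                 pam = built$guide$pam, strand = built$guide$strand,
                 cut_site = built$guide$cut_site,
                 variant_clean = built$guide$variant_clean),
    donor_len = built$donor_len,
    allele_class = built$classification$allele_class,
    payload_in_frame = if (!is.null(built$trap_report))
      built$trap_report$payload_in_frame else NA,
    amplicons = built$validation$amplicons[, c("pair", "length")],
    exclusion_log = built$log,
    files = rel_paths
  )
  list(status = "ok", summary = summary, design = built)
}
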