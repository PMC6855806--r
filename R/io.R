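# Flat-file output: GenBank records and ordering sheets.

#' Write an annotated GenBank flat file
#'
#' Minimal GenBank writer for donor/plasmid/edited-allele records: LOCUS,
#' DEFINITION, FEATURES (misc_feature with /label), ORIGIN.
#'
#' @param seq DNA string.
#' @param path output file.
#' @param name LOCUS name.
#' @param features optional data frame `label`, `start`, `end` (1-based),
#'   optional `strand` ("+"/"-").
#' @param circular is the molecule circular?
#' @param definition DEFINITION line text.
#' @return the path, invisibly.
#' @export
write_genbank <- function(seq, path, name = "record", features = NULL,
                          circular = FALSE, definition = name) {
  n <- nchar(seq)
  lines <- c(
    sprintf("LOCUS       %-17s %d bp    DNA     %-8s SYN %s",
            substr(gsub("[^A-Za-z0-9_.-]", "_", name), 1, 17), n,
            if (circular) "circular" else "linear",
            format(Sys.Date(), "%d-%b-%Y")),
    paste0("DEFINITION  ", definition, "."),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n))
  if (!is.null(features) && nrow(features) > 0L) {
    for (i in seq_len(nrow(features))) {
      loc <- sprintf("%d..%d", features$start[i], features$end[i])
      if (!is.null(features$strand) && identical(features$strand[i], "-")) {
        loc <- sprintf("complement(%s)", loc)
      }
      lines <- c(lines,
                 sprintf("     misc_feature    %s", loc),
                 sprintf("                     /label=\"%s\"", features$label[i]))
    }
  }
  lines <- c(lines, "ORIGIN")
  low <- tolower(seq)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substring(low, off, min(off + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Ordering sheet for a design
#'
#' One row per orderable molecule: long primers for ssDNA designs (with the
#' 5'-phosphorylation flag), or the synthesis insert for dsDNA/plasmid
#' designs, with a vendor-scale note.
#'
#' @param design an `ssdna_design` or `synthesis_construct`.
#' @param gene_id identifier prefix for molecule names.
#' @return data frame `name`, `sequence`, `length`, `phosphorylated_5prime`,
#'   `type`, `note`.
#' @export
ordering_sheet <- function(design, gene_id = "gene") {
  if (inherits(design, "ssdna_design")) {
    p <- design$primers
    data.frame(
      name = paste0(gene_id, c("_drop-in_F", "_drop-in_R")),
      sequence = c(p$forward, p$reverse),
      length = c(p$forward_len, p$reverse_len),
      phosphorylated_5prime = c(p$forward_5prime_phosphorylated,
                                p$reverse_5prime_phosphorylated),
      type = "long_primer",
      note = "order as long-oligo/ultramer scale",
      stringsAsFactors = FALSE)
  } else if (inherits(design, "synthesis_construct")) {
    data.frame(
      name = paste0(gene_id, "_dropin_synthesis"),
      sequence = design$insert_seq,
      length = nchar(design$insert_seq),
      phosphorylated_5prime = FALSE,
      type = "synthesis_fragment",
      note = sprintf("clonal synthesis into a cloning vector; GC %.0f%%",
                     100 * gc_fraction(design$insert_seq)),
      stringsAsFactors = FALSE)
  } else {
    dropin_error("unsupported design type for ordering sheet",
                 "dropin_report_error")
  }
}
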