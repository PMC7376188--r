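#' Locus configurations
#'
#' A locus configuration is the static description every other stage
#' consumes: chromosome class (autosomal, X or Y), GRCh38 repeat-region
#' coordinates (1-based, inclusive at both ends), motif length, the
#' reference repeat structure used as bracketing template and CE anchor,
#' the analysed flanking ranges, and the calling thresholds.
#'
#' The reference structure doubles as the bracketing template: `variable`
#' segments are motif runs whose counts differ between alleles, `fixed`
#' segments are interruptions present in the reference (lowercase when
#' uncounted), `gap` segments are uncalled stretches of stated length, and
#' an optional trailing `tail` segment is a fixed-length terminal unit whose
#' sequence may vary between alleles (its reference sequence is stored as
#' the canonical unit).
#'
#' @param name Locus identifier, e.g. `"D7S820"`.
#' @param chrom_class One of `"autosomal"`, `"X"`, `"Y"`.
#' @param chrom_label Chromosome label as printed in names (`"7"`, `"X"`).
#' @param repeat_start,repeat_end GRCh38 repeat-region interval.
#' @param motif_len Nucleotides per repeat unit (2--6).
#' @param reference_structure A template tibble with columns `unit`,
#'   `count`, `counted`, `kind` (`"variable"`, `"fixed"`, `"gap"`,
#'   `"tail"`) and `gap_len`.
#' @param reference_ce CE designation string of the reference allele, e.g.
#'   `"27"` or `"13"`; the anchor from which all CE designations are
#'   length-offset.
#' @param flank_upstream,flank_downstream Length-2 integer vectors
#'   `c(start, end)` giving the analysed flanking intervals; `NULL` if the
#'   side is not analysed.
#' @param balance_threshold Intralocus balance cutoff in (0, 1]; default
#'   0.60, with per-locus overrides (0.10 for the severely imbalanced
#'   D22S1045).
#' @param analytical_threshold_pct,interpretation_threshold_pct Analytical
#'   and interpretation thresholds as fractions of total locus reads;
#'   defaults 1.5% and 4.5%.
#' @return A `locus_config` object.
#' @export
locus_config <- function(name, chrom_class, chrom_label,
                         repeat_start, repeat_end, motif_len,
                         reference_structure, reference_ce,
                         flank_upstream = NULL, flank_downstream = NULL,
                         balance_threshold = 0.60,
                         analytical_threshold_pct = 0.015,
                         interpretation_threshold_pct = 0.045) {
  cfg <- structure(
    list(
      name = as.character(name),
      chrom_class = match.arg(chrom_class, c("autosomal", "X", "Y")),
      chrom_label = as.character(chrom_label),
      repeat_start = as.integer(repeat_start),
      repeat_end = as.integer(repeat_end),
      motif_len = as.integer(motif_len),
      reference_structure = as_template(reference_structure),
      reference_ce = parse_ce(reference_ce),
      flank_upstream = as_flank_range(flank_upstream),
      flank_downstream = as_flank_range(flank_downstream),
      balance_threshold = as.numeric(balance_threshold),
      analytical_threshold_pct = as.numeric(analytical_threshold_pct),
      interpretation_threshold_pct = as.numeric(interpretation_threshold_pct)
    ),
    class = "locus_config"
  )
  validate_locus_config(cfg)
}

as_flank_range <- function(x) {
  if (is.null(x) || (is.list(x) && !length(x))) return(NULL)
  if (is.list(x)) x <- c(x$start, x$end)
  x <- as.integer(x)
  if (length(x) != 2 || anyNA(x)) {
    stopf("flank range must be c(start, end)", class = "forenseqr_config_error")
  }
  x
}

as_template <- function(x) {
  if (is.data.frame(x)) {
    x <- as_tibble(x)
  } else if (is.list(x)) {
    x <- dplyr::bind_rows(lapply(x, function(seg) {
      tibble(
        unit = toupper(seg$unit %||% NA_character_),
        count = as.integer(seg$count %||% 1L),
        counted = isTRUE(seg$counted %||% TRUE),
        kind = seg$kind %||% "variable",
        gap_len = as.integer(seg$gap_len %||% NA_integer_)
      )
    }))
  } else {
    stopf("reference_structure must be a data frame or list of segments",
          class = "forenseqr_config_error")
  }
  need <- c("unit", "count", "counted", "kind")
  if (!all(need %in% names(x))) {
    stopf("reference_structure needs columns %s", paste(need, collapse = ", "),
          class = "forenseqr_config_error")
  }
  if (!"gap_len" %in% names(x)) x$gap_len <- NA_integer_
  x$unit <- toupper(x$unit)
  x$count <- as.integer(x$count)
  x$gap_len <- as.integer(x$gap_len)
  x$counted <- as.logical(x$counted)
  x$kind <- as.character(x$kind)
  bad <- setdiff(unique(x$kind), c("variable", "fixed", "gap", "tail"))
  if (length(bad)) {
    stopf("unknown template segment kind '%s'", bad[1],
          class = "forenseqr_config_error")
  }
  as_tibble(x)
}

# the template rendered as a concrete reference-allele structure
template_as_structure <- function(template) {
  rows <- lapply(seq_len(nrow(template)), function(i) {
    if (template$kind[i] == "gap") {
      rs_gap(template$gap_len[i])
    } else {
      repeat_structure(
        unit = template$unit[i], count = template$count[i],
        counted = template$counted[i],
        role = switch(template$kind[i], variable = "variable",
                      fixed = "fixed", tail = "tail")
      )
    }
  })
  do.call(rs_bind, rows)
}

reference_length <- function(config) {
  structure_length(template_as_structure(config$reference_structure))
}

validate_locus_config <- function(cfg) {
  err <- function(field, msg) {
    stopf("locus '%s', field '%s': %s", cfg$name, field, msg,
          class = "forenseqr_config_error")
  }
  if (!nzchar(cfg$name)) err("name", "empty locus name")
  if (is.na(cfg$repeat_start) || is.na(cfg$repeat_end) ||
      cfg$repeat_start > cfg$repeat_end) {
    err("repeat_region", "start must be <= end")
  }
  if (is.na(cfg$motif_len) || cfg$motif_len < 2 || cfg$motif_len > 6) {
    err("motif_len", "must be in 2..6")
  }
  for (side in c("flank_upstream", "flank_downstream")) {
    fr <- cfg[[side]]
    if (is.null(fr)) next
    if (fr[1] > fr[2]) err(side, "start must be <= end")
    if (fr[1] <= cfg$repeat_end && fr[2] >= cfg$repeat_start) {
      err(side, "flank range overlaps the repeat region")
    }
  }
  if (!(cfg$balance_threshold > 0 && cfg$balance_threshold <= 1)) {
    err("balance_threshold", "must be in (0, 1]")
  }
  if (!(cfg$analytical_threshold_pct >= 0 &&
        cfg$analytical_threshold_pct <= cfg$interpretation_threshold_pct &&
        cfg$interpretation_threshold_pct <= 1)) {
    err("thresholds", "need 0 <= AT <= IT <= 1")
  }
  tpl <- cfg$reference_structure
  if (nrow(tpl) == 0) err("reference_structure", "empty template")
  var_units <- tpl$unit[tpl$kind %in% c("variable", "tail")]
  if (any(nchar(var_units) != cfg$motif_len)) {
    err("reference_structure",
        "variable/tail segment units must have motif_len nucleotides")
  }
  if (any(tpl$kind == "tail") &&
      (tpl$kind[nrow(tpl)] != "tail" || sum(tpl$kind == "tail") > 1)) {
    err("reference_structure", "at most one tail segment, and it must be last")
  }
  if (any(tpl$kind == "gap" & is.na(tpl$gap_len))) {
    err("reference_structure", "gap segments need gap_len")
  }
  if (any(tpl$kind != "gap" & (is.na(tpl$unit) | !grepl("^[ACGT]+$", tpl$unit)))) {
    err("reference_structure", "segment units must be A/C/G/T")
  }
  cfg
}

#' Load locus configurations from JSON
#'
#' The file holds a top-level list of locus objects whose fields mirror the
#' arguments of [locus_config()]; intervals are `{"start": int, "end": int}`
#' objects and all coordinates are 1-based GRCh38, inclusive at both ends.
#' Thresholds fall back to the panel defaults (AT 1.5%, IT 4.5%, balance
#' 0.60) when a locus omits them.
#'
#' @param path Path to a JSON configuration file.
#' @return A named list of [locus_config()] objects.
#' @export
#' @examples
#' cfgs <- read_locus_config(forenseqr_example("forenseq_strs.json"))
#' names(cfgs)[1:5]
read_locus_config <- function(path) {
  if (!file.exists(path)) {
    stopf("locus config file not found: %s", path,
          class = "forenseqr_config_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  loci <- raw$loci %||% raw
  cfgs <- lapply(loci, function(lc) {
    locus_config(
      name = lc$name,
      chrom_class = lc$chrom_class,
      chrom_label = lc$chrom_label,
      repeat_start = lc$repeat_region$start,
      repeat_end = lc$repeat_region$end,
      motif_len = lc$motif_len,
      reference_structure = lc$reference_structure,
      reference_ce = lc$reference_ce,
      flank_upstream = lc$flank_ranges$upstream,
      flank_downstream = lc$flank_ranges$downstream,
      balance_threshold = lc$balance_threshold %||% 0.60,
      analytical_threshold_pct = lc$analytical_threshold_pct %||% 0.015,
      interpretation_threshold_pct = lc$interpretation_threshold_pct %||% 0.045
    )
  })
  names(cfgs) <- vapply(cfgs, `[[`, character(1), "name")
  if (anyDuplicated(names(cfgs))) {
    stopf("duplicate locus name '%s' in %s",
          names(cfgs)[duplicated(names(cfgs))][1], path,
          class = "forenseqr_config_error")
  }
  cfgs
}

#' Serialize locus configurations back to JSON
#'
#' Loading, serializing and reloading yields equal configurations.
#'
#' @param configs Named list of [locus_config()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_config <- function(configs, path) {
  loci <- lapply(unname(configs), function(cfg) {
    tpl <- cfg$reference_structure
    segs <- lapply(seq_len(nrow(tpl)), function(i) {
      s <- list(unit = tpl$unit[i], count = tpl$count[i],
                counted = tpl$counted[i], kind = tpl$kind[i])
      if (!is.na(tpl$gap_len[i])) s$gap_len <- tpl$gap_len[i]
      if (is.na(s$unit)) s$unit <- NULL
      s
    })
    fr <- list()
    if (!is.null(cfg$flank_upstream)) {
      fr$upstream <- list(start = cfg$flank_upstream[1],
                          end = cfg$flank_upstream[2])
    }
    if (!is.null(cfg$flank_downstream)) {
      fr$downstream <- list(start = cfg$flank_downstream[1],
                            end = cfg$flank_downstream[2])
    }
    list(
      name = cfg$name, chrom_class = cfg$chrom_class,
      chrom_label = cfg$chrom_label,
      repeat_region = list(start = cfg$repeat_start, end = cfg$repeat_end),
      motif_len = cfg$motif_len,
      reference_ce = format_ce(cfg$reference_ce),
      reference_structure = segs,
      flank_ranges = fr,
      balance_threshold = cfg$balance_threshold,
      analytical_threshold_pct = cfg$analytical_threshold_pct,
      interpretation_threshold_pct = cfg$interpretation_threshold_pct
    )
  })
  jsonlite::write_json(list(coordinate_system = "GRCh38 1-based inclusive",
                            loci = loci),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

get_config <- function(configs, locus) {
  cfg <- configs[[locus]]
  if (is.null(cfg)) {
    stopf("no configuration for locus '%s'", locus,
          class = "forenseqr_config_error")
  }
  cfg
}

#' Path to a bundled example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @export
forenseqr_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "forenseqr"))
  } else {
    system.file("extdata", file, package = "forenseqr", mustWork = TRUE)
  }
}

#' @export
print.locus_config <- function(x, ...) {
  cat(sprintf("<locus_config> %s (%s, chr%s) %s-%s motif %dbp CE anchor %s\n",
              x$name, x$chrom_class, x$chrom_label,
              fmt_coord(x$repeat_start), fmt_coord(x$repeat_end),
              x$motif_len, format_ce(x$reference_ce)))
  cat("  template:", format_segments(template_as_structure(x$reference_structure)),
      "\n")
  invisible(x)
}
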