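profile_by_name <- function(name) {
  switch(name,
         "hine-mo" = hine_mo_profile("consensus"),
         "hine-mo-genomic" = hine_mo_profile("genomic"),
         "dine-1" = dine1_profile(),
         "helitron" = helitron_profile(),
         "proto-helentron" = proto_helentron_profile(),
         stop("unknown profile: ", name, call. = FALSE))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

stamp_file <- function(path, hash) {
  lines <- readLines(path, warn = FALSE)
  header <- sprintf("# helentronscan %s config_md5=%s",
                    as.character(utils::packageVersion("helentronscan")), hash)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Run the full annotation pipeline
#'
#' Executes scan, Rep classification, family/subfamily assignment and
#' empty-site/target-site analysis in order, writing GFF3/BED
#' annotations, a family TSV, a site TSV and a JSON report into
#' `config$out_dir`.  Every output embeds the tool version and an MD5
#' hash of the effective configuration.  On a stage failure, outputs
#' written so far are renamed with a `.partial` suffix and the error is
#' re-raised.
#'
#' @param config a named list (or path to a JSON file) with entries
#'   `genome` (FASTA path or named character vector), `profile` (preset
#'   name, default `"hine-mo-genomic"`), `species_code` (default "Xx"),
#'   `out_dir`, `seed`, `flank`, `min_identity`, `min_coverage`,
#'   `check_coding`, `seeds`.
#' @return invisibly, a list with `annotations`, `families`, `sites`,
#'   `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    for (f in written) if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
    stop(e)
  }
  tryCatch({
    genome <- config$genome
    if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
      genome <- read_fasta(genome, "dna")
    } else if (is.character(genome) && length(genome) == 1L &&
               !grepl("^[ACGTNacgtn]+$", genome)) {
      stop("genome file not found: ", genome, call. = FALSE)
    }
    profile <- config$profile %||% "hine-mo-genomic"
    if (is.character(profile)) profile <- profile_by_name(profile)
    if (!is.null(config$slack)) profile$slack <- as.integer(config$slack)
    # paths are excluded from the hash: the same analysis written to a
    # different directory must stamp identically
    hash <- config_hash(config[setdiff(names(config),
                                       c("genome", "out_dir"))])
    if (!is.null(config$seed)) set.seed(as.integer(config$seed))

    anns <- scan_genome(genome, profile, seeds = config$seeds,
                        check_coding = config$check_coding %||% TRUE)

    gff <- file.path(out_dir, "annotations.gff3")
    bed <- file.path(out_dir, "annotations.bed")
    seqlens <- vapply(genome, nchar, integer(1))
    write_annotations(anns, gff, "gff3", seqlens = seqlens)
    write_annotations(anns, bed, "bed", seqlens = seqlens)
    written <- c(written, stamp_file(gff, hash), stamp_file(bed, hash))

    fam_tab <- NULL
    if (length(anns)) {
      seqs <- vapply(anns, function(a) {
        s <- substr0(genome[[a$element$seqid]], a$element$start, a$element$end)
        if (a$element$strand == "-") revcomp(s) else s
      }, character(1))
      names(seqs) <- vapply(anns, `[[`, character(1), "id")
      subtirs <- lapply(anns, function(a)
        Filter(nzchar, c(a$subtir5$seq %||% "", a$subtir3$seq %||% "")))
      names(subtirs) <- names(seqs)
      autonomous <- vapply(anns, function(a)
        isTRUE(a$evidence$coding), logical(1))
      names(autonomous) <- names(seqs)
      fam_tab <- classify_elements(seqs, subtirs, autonomous,
                                   species_code = config$species_code %||% "Xx")
      fam_tab$structure_type <- vapply(anns, `[[`, character(1),
                                       "structure_type")[
        match(fam_tab$element_id, names(seqs))]
    }
    fam_path <- file.path(out_dir, "families.tsv")
    utils::write.table(fam_tab %||% data.frame(), fam_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, stamp_file(fam_path, hash))

    flank <- as.integer(config$flank %||% 50L)
    sp <- empty_site_params(flank = flank,
                            min_identity = config$min_identity %||% 0.90,
                            min_coverage = config$min_coverage %||% 0.90)
    site_rows <- list()
    for (a in anns) {
      iv <- a$element
      q <- tryCatch(build_chimeric_query(genome, iv, flank), error = function(e) NULL)
      hits <- NULL; rep_line <- NULL
      if (!is.null(q)) {
        fam_of <- if (!is.null(fam_tab))
          fam_tab$family[match(a$id, fam_tab$element_id)] else NA
        mask <- NULL
        if (!is.null(fam_tab) && !is.na(fam_of)) {
          sibs <- fam_tab$element_id[fam_tab$family == fam_of & fam_tab$element_id != a$id]
          if (length(sibs)) {
            sib_anns <- anns[vapply(anns, `[[`, character(1), "id") %in% sibs]
            mask <- do.call(rbind, lapply(sib_anns, function(s)
              data.frame(seqid = s$element$seqid, start = s$element$start,
                         end = s$element$end)))
          }
        }
        hits <- find_empty_sites(q, genome, sp, insertion = iv, mask = mask)
      }
      best <- if (!is.null(hits) && nrow(hits)) hits[1, , drop = FALSE] else NULL
      rep <- analyze_target_site(genome, iv, empty = best)
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        element_id = a$id, seqid = iv$seqid, start = iv$start, end = iv$end,
        strand = iv$strand,
        empty_seqid = best$seqid %||% NA_character_,
        empty_start = best$start %||% NA_integer_,
        empty_end = best$end %||% NA_integer_,
        empty_identity = best$identity %||% NA_real_,
        empty_coverage = best$coverage %||% NA_real_,
        left_t_run = rep$left_t_run, right_t_run = rep$right_t_run,
        tt_at_insertion = rep$tt_at_insertion,
        tsd = rep$tsd, at_insertion = rep$at_insertion,
        stringsAsFactors = FALSE)
    }
    sites_tab <- if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame()
    sites_path <- file.path(out_dir, "sites.tsv")
    utils::write.table(sites_tab, sites_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, stamp_file(sites_path, hash))

    types <- vapply(anns, `[[`, character(1), "structure_type")
    diagnostics <- character(0)
    copy_number <- NULL
    if (!is.null(fam_tab) && nrow(fam_tab)) {
      agg <- stats::aggregate(cbind(autonomous = fam_tab$autonomous,
                                    non_autonomous = !fam_tab$autonomous),
                              by = list(family = fam_tab$family), FUN = sum)
      copy_number <- agg
      low <- agg$family[agg$non_autonomous <= agg$autonomous & agg$autonomous > 0]
      if (length(low)) {
        diagnostics <- c(diagnostics, sprintf(
          paste0("family %d: non-autonomous copy number (%d) does not exceed ",
                 "the autonomous partner's (%d); atypical for these elements"),
          low, agg$non_autonomous[match(low, agg$family)],
          agg$autonomous[match(low, agg$family)]))
      }
    }
    report <- list(
      tool = "helentronscan",
      version = as.character(utils::packageVersion("helentronscan")),
      config = config[setdiff(names(config), c("genome", "out_dir"))],
      config_md5 = hash,
      n_elements = length(anns),
      structure_type_counts = as.list(table(types)),
      copy_number = copy_number,
      n_empty_sites = if (nrow(sites_tab)) sum(!is.na(sites_tab$empty_start)) else 0L,
      diagnostics = diagnostics)
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
    written <- c(written, report_path)
    invisible(list(annotations = anns, families = fam_tab,
                   sites = sites_tab, report = report))
  }, error = on_fail)
}
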