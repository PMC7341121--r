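# End-to-end pipeline: design -> simulate (treated + matched unedited
# control) -> align -> profile -> call, with every stage's artifact written
# before the next stage reads it. Deterministic for a fixed seed; the design
# stage does not consume randomness at all.

#' Plot treated vs control deletion profiles
#'
#' Per-position deletion counts for two samples, mirroring the standard
#' amplicon-editing readout: x = reference position (optionally offset to
#' genomic coordinates), y = number of deletions, one series per sample, the
#' sgRNA interval annotated.
#'
#' @param treated,control `deletion_profile`s.
#' @param sgrna_interval Optional 0-based half-open interval to shade.
#' @param offset Added to positions for genomic coordinates.
#' @return A ggplot object.
#' @export
plot_profiles <- function(treated, control, sgrna_interval = NULL,
                          offset = 0L) {
  df <- rbind(data.frame(position = treated$position + offset,
                         deletions = treated$deletions, sample = "treated"),
              data.frame(position = control$position + offset,
                         deletions = control$deletions, sample = "control"))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = position, y = deletions,
                                         colour = sample))
  if (!is.null(sgrna_interval)) {
    gg <- gg + ggplot2::annotate("rect", xmin = sgrna_interval[1L] + offset,
                                 xmax = sgrna_interval[2L] + offset,
                                 ymin = -Inf, ymax = Inf, alpha = 0.15,
                                 fill = "red")
  }
  gg + ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(treated = "blue",
                                            control = "red")) +
    ggplot2::labs(x = "reference position", y = "deletions",
                  caption = sprintf("mean coverage: treated %.0f, control %.0f",
                                    attr(treated, "mean_coverage"),
                                    attr(control, "mean_coverage"))) +
    ggplot2::theme_minimal()
}

stage <- function(name, expr) {
  log_msg("info", "stage ", name, " started")
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline from a configuration
#'
#' Stages: library design (in-silico PCR), mosaic simulation of a treated
#' sample and a matched unedited control, adapter trimming + alignment,
#' per-position deletion profiling, and the editing call. All artifacts are
#' written under `cfg$out_dir`: `design.json`, `amplicon.fa`,
#' `{treated,control}.fastq`, `treated_truth.tsv`, `{treated,control}.sam`,
#' `{treated,control}_profile.tsv`, `edit_call.json`, `profiles.pdf`.
#'
#' @param cfg A `pipeline_config` ([read_config()] / [config_defaults()]);
#'   when `cfg$reference`/`cfg$primers` are empty the bundled synthetic locus
#'   and published primer table are used.
#' @return The `edit_call`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg) {
  old <- options(crisprseq.log_level = cfg$log_level)
  on.exit(options(old))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)

  design <- stage("design", {
    primers_path <- if (nzchar(cfg$primers)) cfg$primers else
      system.file("extdata", "table1_primers.tsv", package = "crisprseq")
    if (!file.exists(primers_path)) {
      stop("primer table not found: ", primers_path)
    }
    primers <- read_primer_table(primers_path)
    fwd <- primers[[cfg$fwd_primer]]
    rev <- primers[[cfg$rev_primer]]
    if (is.null(fwd) || is.null(rev)) {
      stop("primer '", cfg$fwd_primer, "' or '", cfg$rev_primer,
           "' not in table")
    }
    target <- if (nzchar(cfg$reference)) {
      if (!file.exists(cfg$reference)) {
        stop("reference file not found: ", cfg$reference)
      }
      fa <- read_fasta(cfg$reference)
      genomic_target(names(fa)[1L], fa[[1L]], 0L, nchar(fa[[1L]]))
    } else {
      synthetic_target(fwd, rev)
    }
    d <- library_design(target, fwd, rev)
    jsonlite::write_json(list(
      target = target$name, amplicon_start = d$amplicon$start,
      amplicon_end = d$amplicon$end, pcr1_len = d$pcr1_len,
      pcr2_len = d$pcr2_len, cut_site = target$cut_site,
      fwd_primer = fwd$name, rev_primer = rev$name),
      out("design.json"), auto_unbox = TRUE, null = "null")
    write_fasta(stats::setNames(d$amplicon$seq, target$name),
                out("amplicon.fa"))
    log_msg("info", "design: amplicon ", nchar(d$amplicon$seq),
            " bp, PCR2 molecule ", d$pcr2_len, " bp")
    d
  })

  seed <- as.integer(cfg$seed)
  sims <- stage("simulate", {
    model <- edit_model(cfg$edited_cell_fraction, cfg$per_allele_edit_prob,
                        cfg$del_len_mean, cfg$max_del_len,
                        cfg$left_extent_frac, cfg$insertion_prob)
    null_model <- edit_model(0, 0, cfg$del_len_mean, cfg$max_del_len,
                             cfg$left_extent_frac)
    params <- function(s) read_sim_params(cfg$n_reads, cfg$read_len,
                                          cfg$subst_error_rate, s)
    treated <- simulate_reads(
      simulate_population(design, model, cfg$n_alleles, seed),
      params(seed + 1L))
    control <- simulate_reads(
      simulate_population(design, null_model, cfg$n_alleles, seed + 2L),
      params(seed + 3L))
    write_read_set(treated, out("treated.fastq"), out("treated_truth.tsv"))
    write_read_set(control, out("control.fastq"))
    log_msg("info", "simulated ", nrow(treated$reads), " + ",
            nrow(control$reads), " reads")
    list(treated = treated, control = control)
  })

  alns <- stage("align", {
    scheme <- scoring_scheme()
    a <- list(treated = align_set(read_fastq(out("treated.fastq")), design,
                                  scheme),
              control = align_set(read_fastq(out("control.fastq")), design,
                                  scheme))
    write_sam(a$treated, design$target$name, nchar(design$amplicon$seq),
              out("treated.sam"))
    write_sam(a$control, design$target$name, nchar(design$amplicon$seq),
              out("control.sam"))
    log_msg("info", "aligned treated ", a$treated$summary$n_aligned, "/",
            a$treated$summary$n_reads, ", control ",
            a$control$summary$n_aligned, "/", a$control$summary$n_reads)
    a
  })

  profs <- stage("profile", {
    pt <- deletion_profile(out("treated.sam"), sample = "treated")
    pc <- deletion_profile(out("control.sam"), sample = "control")
    write_profile(pt, out("treated_profile.tsv"))
    write_profile(pc, out("control_profile.tsv"))
    list(treated = pt, control = pc)
  })

  call <- stage("call", {
    ec <- call_editing(alns$treated, alns$control, alpha = cfg$alpha,
                       min_del_len = cfg$min_del_len)
    jsonlite::write_json(unclass(ec), out("edit_call.json"),
                         auto_unbox = TRUE, digits = NA)
    log_msg("info", "edit call: detected=", ec$detected, " p=",
            format(ec$p_value))
    ec
  })

  stage("plot", {
    tg <- design$target
    sg <- if (!is.null(tg$pam_offset)) {
      c(tg$pam_offset - 20L, tg$pam_offset + 3L) - design$amplicon$start
    }
    gg <- plot_profiles(profs$treated, profs$control, sg)
    grDevices::pdf(out("profiles.pdf"), width = 7, height = 4)
    print(gg)
    grDevices::dev.off()
  })

  invisible(call)
}

#' Deleted-read fraction check for real amplicon data
#'
#' Runs trimming, alignment and [edited_read_fraction()] on a user-supplied
#' FASTQ of real amplicon reads (e.g. downloaded from SRA project SRP257957;
#' this package does not fetch data) and reports whether the deleted-read
#' fraction is at or below the expected ceiling for a mosaic sample.
#'
#' @param fastq Path to the downloaded FASTQ (plain or gzip).
#' @param design A `library_design` for the amplicon.
#' @param max_fraction Expected ceiling on the deleted-read fraction
#'   (default 0.04: mosaic samples show 4% or fewer deleted reads even when
#'   ~10% of cells are edited, because of primer-site dropout).
#' @param scheme A `scoring_scheme`.
#' @return List with `fraction`, `n_deleted`, `n_aligned`, `within_ceiling`.
#' @export
sra_fraction_check <- function(fastq, design, max_fraction = 0.04,
                               scheme = scoring_scheme()) {
  if (!is.character(fastq) || length(fastq) != 1L || !file.exists(fastq)) {
    stop("sra_fraction_check: FASTQ not found at '", fastq,
         "'. Download the run (e.g. from SRA project SRP257957 with ",
         "prefetch/fasterq-dump) and pass its local path; this package ",
         "does not fetch remote data.", call. = FALSE)
  }
  aln <- align_set(fastq, design, scheme)
  frac <- edited_read_fraction(aln)
  c(frac, list(within_ceiling = frac$fraction <= max_fraction))
}
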