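# Synthetic multi-sample fixture generator. Emits the four on-disk formats
# the pipeline consumes (FIMO TSV, narrowPeak, bedpe, GTF) plus a ground
# truth table, with a planted probabilistic dependency between window
# features and loop status so every downstream module has a known answer.

#' Default configuration of the synthetic loop study
#'
#' The generative model: true loops carry a convergent motif pair at their
#' anchors with elevated FIMO scores (conserved sites score higher); CTCF
#' occupies both anchor motifs with probability `ctcf_emission[1]` and
#' RAD21 accompanies occupied loops; each histone mark appears in each of
#' the three loop windows with probability `mark_emission[1]`. Background
#' motifs are occupied with probability `ctcf_emission[2]` and background
#' mark peaks are scattered so that a random 1-kb window is hit with
#' probability about `mark_emission[2]`. Case samples replay the control
#' model with the CTCF/RAD21 occupancy of a `case_disruption` fraction of
#' true loops deleted; `cluster_size` of the disrupted loops are
#' co-located and covered by one "hub" gene so the gene ranking has a
#' unique planted answer. Decoy loop calls straddle the PET/FDR/span filters.
#'
#' @param ... Overrides of any default field.
#' @return A named list of generator settings.
#' @export
loop_study_config <- function(...) {
  cfg <- list(
    n_chroms = 4,
    chrom_length = 3e7,
    n_background_motifs = 8000,
    motif_width = 19,
    n_true_loops = 2000,
    n_decoy_loops = 200,
    span_range = c(2000, 2e6),
    ctcf_emission = c(loop = 1.0, background = 0.1),
    mark_emission = c(loop = 0.9, background = 0.1),
    marks = c("h3k4me1", "h3k9me3", "h3k27me3", "h3k27ac"),
    anchor_halfwidth = 50,
    peak_halfwidth = 100,
    motif_score_mean = c(loop = 18, background = 12),
    motif_score_sd = 2,
    n_control_samples = 3,
    n_case_samples = 1,
    case_disruption = 0.1,
    cluster_size = 8,
    n_extra_genes = 100,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config field(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  modifyList(cfg, overrides)
}

#' Generate a multi-sample synthetic loop study
#'
#' Writes, under `out_dir`: `loops.bedpe`, `motifs.tsv` (FIMO layout),
#' `genes.gtf`, `ground_truth.tsv`, and one subdirectory per sample
#' (`control1..N`, `case1..M`) holding `ctcf.narrowPeak`,
#' `rad21.narrowPeak` and one narrowPeak per histone mark. All files parse
#' back through the package readers. The same seed yields a byte-identical
#' file set.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A list from [loop_study_config()].
#' @return Invisibly, a list: `dir`, `samples` (tibble of sample names,
#'   conditions and directories), `ground_truth` (per-loop status table)
#'   and `config`.
#' @export
simulate_loop_study <- function(out_dir, config = loop_study_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(config$seed, {
    world <- simulate_world(config)
    samples <- tibble(
      sample = c(sprintf("control%d", seq_len(config$n_control_samples)),
                 sprintf("case%d", seq_len(config$n_case_samples))),
      condition = c(rep("control", config$n_control_samples),
                    rep("case", config$n_case_samples))
    )
    samples$dir <- file.path(out_dir, samples$sample)
    write_fimo_file(world$motifs, file.path(out_dir, "motifs.tsv"))
    write_bedpe_file(world$loops, file.path(out_dir, "loops.bedpe"))
    write_gtf_file(world$genes, file.path(out_dir, "genes.gtf"))
    readr::write_tsv(world$ground_truth,
                     file.path(out_dir, "ground_truth.tsv"), progress = FALSE)
    for (i in seq_len(nrow(samples))) {
      emit_sample_tracks(world, config, samples$condition[i], samples$dir[i])
    }
    invisible(list(dir = out_dir, samples = samples,
                   ground_truth = world$ground_truth, config = config))
  })
}

# Draw the condition-independent world: motifs, loops, genes, truth.
simulate_world <- function(config) {
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  mw <- config$motif_width
  L <- config$chrom_length

  # -- true loops: span log-uniform, both anchors inside the chromosome ----
  n_true <- config$n_true_loops
  k <- config$cluster_size
  if (n_true < k + 1) abort("Need more true loops than the disruption cluster size.")
  span <- round(10^runif(n_true, log10(config$span_range[1]),
                         log10(config$span_range[2])))
  chrom <- sample(chroms, n_true, replace = TRUE)
  mid1 <- round(runif(n_true, 1e4, L - span - 1e4))

  # the first cluster_size true loops form the disruption cluster on chr1:
  # close together so a single hub gene can span every inner region
  chrom[1:k] <- chroms[1]
  span[1:k] <- round(runif(k, 5e4, min(2e5, 0.02 * L)))
  spacing <- min(4e5, 0.4 * L / k)
  mid1[1:k] <- round(0.3 * L + (seq_len(k) - 1) * spacing +
                       runif(k, 0, 0.02 * spacing))
  mid2 <- mid1 + span
  if (any(mid2 + 1e4 > L)) abort("Chromosome too short for configured spans.")

  # anchors of distinct loops stay > 1.2 kb apart so no anchor window can
  # capture another loop's motif; redraw colliding placements
  occupied <- lapply(setNames(chroms, chroms), function(ch) {
    c(mid1[1:k][chrom[1:k] == ch], mid2[1:k][chrom[1:k] == ch])
  })
  min_gap <- 1200
  for (i in (k + 1):n_true) {
    for (try in 1:100) {
      occ <- occupied[[chrom[i]]]
      ok <- length(occ) == 0 ||
        (min(abs(occ - mid1[i])) >= min_gap &&
           min(abs(occ - mid2[i])) >= min_gap)
      if (ok) break
      mid1[i] <- round(runif(1, 1e4, L - span[i] - 1e4))
      mid2[i] <- mid1[i] + span[i]
      if (try == 100) abort("Cannot place loops without anchor collisions; lower n_true_loops.")
    }
    occupied[[chrom[i]]] <- c(occupied[[chrom[i]]], mid1[i], mid2[i])
  }

  true_loops <- tibble(
    loop_id = sprintf("loop_%05d", seq_len(n_true)),
    status = "true", chrom = chrom, mid1 = mid1, mid2 = mid2,
    span = as.integer(span)
  )

  # anchor motifs: convergent, elevated scores
  loop_motifs <- bind_rows(
    tibble(chrom = chrom, mid = mid1, strand = "+",
           owner = true_loops$loop_id, role = "anchor1"),
    tibble(chrom = chrom, mid = mid2, strand = "-",
           owner = true_loops$loop_id, role = "anchor2")
  ) |>
    mutate(
      start = as.integer(.data$mid - mw %/% 2),
      end = as.integer(.data$start + mw),
      score = round(rnorm(n(), config$motif_score_mean[["loop"]],
                          config$motif_score_sd), 4),
      p_value = signif(10^-runif(n(), 4, 8), 4)
    )

  bg_motifs <- tibble(
    chrom = sample(chroms, config$n_background_motifs, replace = TRUE),
    mid = round(runif(config$n_background_motifs, 1e4, L - 1e4)),
    strand = sample(c("+", "-"), config$n_background_motifs, replace = TRUE),
    owner = NA_character_, role = "background"
  )
  # keep anchor windows free of background motifs: the planted anchor site
  # is the best (and only) candidate motif of its own window
  near_anchor <- logical(nrow(bg_motifs))
  for (ch in chroms) {
    planted <- sort(c(mid1[chrom == ch], mid2[chrom == ch]))
    rows <- which(bg_motifs$chrom == ch)
    if (length(planted) == 0 || length(rows) == 0) next
    j <- findInterval(bg_motifs$mid[rows], planted)
    d_left <- abs(bg_motifs$mid[rows] - planted[pmax(j, 1)])
    d_right <- abs(planted[pmin(j + 1, length(planted))] -
                     bg_motifs$mid[rows])
    near_anchor[rows] <- pmin(d_left, d_right) < 700
  }
  bg_motifs <- bg_motifs[!near_anchor, , drop = FALSE]
  bg_motifs <- bg_motifs |>
    mutate(
      start = as.integer(.data$mid - mw %/% 2),
      end = as.integer(.data$start + mw),
      score = round(rnorm(n(), config$motif_score_mean[["background"]],
                          config$motif_score_sd), 4),
      p_value = signif(10^-runif(n(), 3, 6), 4)
    )
  motifs <- bind_rows(loop_motifs, bg_motifs) |>
    arrange(.data$chrom, .data$start)

  # -- decoy loop calls straddling the quality filters ---------------------
  n_decoy <- config$n_decoy_loops
  decoys <- NULL
  if (n_decoy > 0) {
    kinds <- rep(c("low_pet", "high_fdr", "no_motif", "bad_span"),
                 length.out = n_decoy)
    d_span <- ifelse(kinds == "bad_span",
                     sample(c(1000, 2.5e6), n_decoy, replace = TRUE),
                     round(10^runif(n_decoy, log10(5e3), log10(5e5))))
    d_chrom <- sample(chroms, n_decoy, replace = TRUE)
    d_mid1 <- round(runif(n_decoy, 1e4, L - max(d_span) - 2e4))
    decoys <- tibble(
      loop_id = sprintf("loop_%05d", n_true + seq_len(n_decoy)),
      status = paste0("decoy_", kinds), chrom = d_chrom,
      mid1 = d_mid1, mid2 = d_mid1 + d_span, span = as.integer(d_span)
    )
    # decoys other than "no_motif" reuse background motif positions? They
    # simply point at arbitrary coordinates; no planted motifs, so they are
    # removed as unlabeled unless a background motif happens to sit there.
  }
  all_loops <- bind_rows(true_loops, decoys)

  # -- bedpe fields --------------------------------------------------------
  aw <- config$anchor_halfwidth
  loops_bedpe <- all_loops |>
    mutate(
      start1 = as.integer(.data$mid1 - aw), end1 = as.integer(.data$mid1 + aw),
      start2 = as.integer(.data$mid2 - aw), end2 = as.integer(.data$mid2 + aw),
      pet_count = ifelse(.data$status == "decoy_low_pet", 1L,
                         2L + stats::rpois(n(), 4)),
      fdr = ifelse(.data$status == "decoy_high_fdr",
                   round(runif(n(), 0.06, 0.3), 4),
                   round(runif(n(), 0, 0.05), 4))
    )

  # -- disruption set ------------------------------------------------------
  n_disrupt <- max(k, round(config$case_disruption * n_true))
  disrupted_ids <- c(true_loops$loop_id[1:k],
                     sample(true_loops$loop_id[-(1:k)], n_disrupt - k))
  if (config$case_disruption == 0) disrupted_ids <- character(0)

  # -- genes ---------------------------------------------------------------
  hub <- tibble(
    gene_id = "GENE_HUB", gene_name = "HUBGENE", chrom = chroms[1],
    start = as.integer(min(mid1[1:k]) - 1000),
    end = as.integer(max(mid2[1:k]) + 1000), strand = "+"
  )
  inner_len <- pmax(200L, as.integer(round(0.6 * true_loops$span)))
  dedicated <- tibble(
    gene_id = sprintf("GENE_%05d", seq_len(n_true)),
    gene_name = sprintf("G%05d", seq_len(n_true)),
    chrom = true_loops$chrom,
    start = as.integer(true_loops$mid1 +
                         round(0.2 * true_loops$span)),
    end = as.integer(true_loops$mid1 + round(0.2 * true_loops$span) +
                       inner_len),
    strand = sample(c("+", "-"), n_true, replace = TRUE)
  )
  extra <- if (config$n_extra_genes > 0) {
    glen <- round(10^runif(config$n_extra_genes, 3.3, 4.7))
    gstart <- round(runif(config$n_extra_genes, 1e4, L - 1e5))
    tibble(
      gene_id = sprintf("GENE_X%04d", seq_len(config$n_extra_genes)),
      gene_name = sprintf("GX%04d", seq_len(config$n_extra_genes)),
      chrom = sample(chroms, config$n_extra_genes, replace = TRUE),
      start = as.integer(gstart), end = as.integer(gstart + glen),
      strand = sample(c("+", "-"), config$n_extra_genes, replace = TRUE)
    )
  } else NULL
  genes <- bind_rows(hub, dedicated, extra) |>
    arrange(.data$chrom, .data$start)

  planted_gene <- setNames(dedicated$gene_name, true_loops$loop_id)
  planted_gene[true_loops$loop_id[1:k]] <- "HUBGENE"

  ground_truth <- loops_bedpe |>
    mutate(
      disrupted = .data$loop_id %in% disrupted_ids,
      planted_gene = ifelse(.data$status == "true",
                            unname(planted_gene[.data$loop_id]),
                            NA_character_)
    ) |>
    select("loop_id", "status", "chrom", "start1", "end1", "start2", "end2",
           "span", "pet_count", "fdr", "disrupted", "planted_gene")

  list(motifs = motifs, loops = loops_bedpe, genes = genes,
       true_loops = true_loops, loop_motifs = loop_motifs,
       disrupted_ids = disrupted_ids, ground_truth = ground_truth)
}

# Draw one sample's peak tracks and write its narrowPeak files.
emit_sample_tracks <- function(world, config, condition, sample_dir) {
  dir.create(sample_dir, recursive = TRUE, showWarnings = FALSE)
  pw <- config$peak_halfwidth
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  disrupted <- world$loop_motifs$owner %in% world$disrupted_ids &
    condition == "case"

  # CTCF: anchor motifs of intact true loops occupied w.p. ctcf_emission[1];
  # background motifs w.p. ctcf_emission[2]; disrupted anchors never.
  lm <- world$loop_motifs
  occ <- runif(nrow(lm)) < config$ctcf_emission[[1]] & !disrupted
  bg <- world$motifs[world$motifs$role == "background", , drop = FALSE]
  bg_occ <- runif(nrow(bg)) < config$ctcf_emission[[2]]
  ctcf <- bind_rows(
    tibble(chrom = lm$chrom[occ], start = lm$mid[occ] - pw,
           end = lm$mid[occ] + pw),
    tibble(chrom = bg$chrom[bg_occ], start = bg$mid[bg_occ] - pw,
           end = bg$mid[bg_occ] + pw)
  )
  write_narrowpeak_file(ctcf, file.path(sample_dir, "ctcf.narrowPeak"))

  # RAD21 at the base of intact occupied loops: one or both anchors
  tl <- world$true_loops
  intact <- !(tl$loop_id %in% world$disrupted_ids & condition == "case")
  rad_emit <- runif(nrow(tl)) < config$ctcf_emission[[1]] & intact
  rad_side <- sample(c("start", "end", "both"), nrow(tl), replace = TRUE,
                     prob = c(0.35, 0.35, 0.3))
  rad <- bind_rows(
    tibble(chrom = tl$chrom, mid = tl$mid1)[rad_emit & rad_side != "end", ],
    tibble(chrom = tl$chrom, mid = tl$mid2)[rad_emit & rad_side != "start", ]
  ) |>
    mutate(start = .data$mid - pw, end = .data$mid + pw) |>
    select("chrom", "start", "end")
  # sparse background RAD21 so negative sampling has something to exclude
  n_bg_rad <- round(0.02 * config$n_background_motifs)
  rad_bg <- tibble(
    chrom = sample(chroms, n_bg_rad, replace = TRUE),
    start = round(runif(n_bg_rad, 1e4, config$chrom_length - 1e4))
  ) |>
    mutate(end = .data$start + 2 * pw)
  write_narrowpeak_file(bind_rows(rad, rad_bg),
                        file.path(sample_dir, "rad21.narrowPeak"))

  # histone marks: emitted per loop window w.p. mark_emission[1]; background
  # scattered at a density giving ~mark_emission[2] per kb
  for (m in config$marks) {
    peaks <- NULL
    for (side in c("mid1", "mid2", "inner")) {
      emit <- runif(nrow(tl)) < config$mark_emission[[1]]
      if (!any(emit)) next
      centre <- switch(side,
        mid1 = tl$mid1[emit],
        mid2 = tl$mid2[emit],
        inner = round((tl$mid1[emit] + tl$mid2[emit]) / 2))
      peaks <- bind_rows(peaks, tibble(
        chrom = tl$chrom[emit], start = centre - pw, end = centre + pw))
    }
    n_bg <- round(config$mark_emission[[2]] *
                    config$n_chroms * config$chrom_length / 1000)
    if (n_bg > 0) {
      bgp <- tibble(
        chrom = sample(chroms, n_bg, replace = TRUE),
        start = round(runif(n_bg, 0, config$chrom_length - 2 * pw))
      ) |>
        mutate(end = .data$start + 2 * pw)
      peaks <- bind_rows(peaks, bgp)
    }
    if (is.null(peaks)) {
      peaks <- tibble(chrom = character(), start = integer(), end = integer())
    }
    write_narrowpeak_file(peaks, file.path(sample_dir,
                                           paste0(m, ".narrowPeak")))
  }
  invisible(sample_dir)
}

#' Default configuration of the synthetic binding study
#'
#' Bound sites (a `frac_bound` fraction) get each 25-bp bin of each track
#' hit with probability `bin_emission[1]`; unbound sites with probability
#' `bin_emission[2]`. Bound sites also carry elevated FIMO scores. CTCF
#' ChIP peaks (the labels) cover bound motifs exactly, so labels are clean
#' while track evidence is noisy.
#'
#' @param ... Overrides of any default field.
#' @return A named list of generator settings.
#' @export
binding_study_config <- function(...) {
  cfg <- list(
    n_chroms = 4,
    chrom_length = 3e7,
    n_sites = 3000,
    motif_width = 19,
    frac_bound = 0.3,
    span = 500,
    bin = 25,
    tracks = c("dnase", "h3k4me3", "h3k27me3", "h3k27ac"),
    bin_emission = c(bound = 0.7, unbound = 0.1),
    motif_score_mean = c(bound = 17, unbound = 13),
    motif_score_sd = 2,
    n_control_samples = 3,
    n_case_samples = 1,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config field(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  modifyList(cfg, overrides)
}

#' Generate a multi-sample synthetic binding study
#'
#' Writes `sites.tsv` (FIMO layout) plus one subdirectory per sample with
#' `ctcf.narrowPeak` (the occupancy labels) and one narrowPeak per track.
#' Supports the three evaluation regimes: within-sample split,
#' leave-one-control-out, and controls-to-case.
#'
#' @param out_dir Output directory.
#' @param config A list from [binding_study_config()].
#' @return Invisibly: `dir`, `samples` tibble, `sites` tibble with the
#'   planted `bound` status, and `config`.
#' @export
simulate_binding_study <- function(out_dir, config = binding_study_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(config$seed, {
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    mw <- config$motif_width
    n <- config$n_sites
    bound <- runif(n) < config$frac_bound
    # sites sit on a 600-bp grid so site regions never overlap and the
    # planted occupancy is exactly what ChIP overlap recovers
    site_chrom <- sample(chroms, n, replace = TRUE)
    mid <- integer(n)
    for (ch in chroms) {
      rows <- which(site_chrom == ch)
      slots <- seq(1e4, config$chrom_length - 1e4, by = 600)
      if (length(rows) > length(slots)) {
        abort("Too many sites for the chromosome length.")
      }
      mid[rows] <- sample(slots, length(rows))
    }
    sites <- tibble(
      chrom = site_chrom,
      mid = mid,
      strand = sample(c("+", "-"), n, replace = TRUE),
      bound = bound
    ) |>
      mutate(
        start = as.integer(.data$mid - mw %/% 2),
        end = as.integer(.data$start + mw),
        score = round(rnorm(n, ifelse(bound,
                                      config$motif_score_mean[["bound"]],
                                      config$motif_score_mean[["unbound"]]),
                            config$motif_score_sd), 4),
        p_value = signif(10^-runif(n, 3, 7), 4)
      ) |>
      arrange(.data$chrom, .data$start)
    write_fimo_file(sites, file.path(out_dir, "sites.tsv"))
    readr::write_tsv(select(sites, "chrom", "start", "end", "strand",
                            "score", "bound"),
                     file.path(out_dir, "ground_truth.tsv"), progress = FALSE)

    samples <- tibble(
      sample = c(sprintf("control%d", seq_len(config$n_control_samples)),
                 sprintf("case%d", seq_len(config$n_case_samples))),
      condition = c(rep("control", config$n_control_samples),
                    rep("case", config$n_case_samples))
    )
    samples$dir <- file.path(out_dir, samples$sample)
    n_bins <- config$span %/% config$bin
    for (i in seq_len(nrow(samples))) {
      dir.create(samples$dir[i], recursive = TRUE, showWarnings = FALSE)
      ctcf <- tibble(chrom = sites$chrom[sites$bound],
                     start = sites$start[sites$bound],
                     end = sites$end[sites$bound])
      write_narrowpeak_file(ctcf, file.path(samples$dir[i], "ctcf.narrowPeak"))
      for (tr in config$tracks) {
        p <- ifelse(sites$bound, config$bin_emission[[1]],
                    config$bin_emission[[2]])
        hit <- matrix(runif(n * n_bins) < rep(p, n_bins), nrow = n)
        which_hit <- which(hit, arr.ind = TRUE)
        b_start <- sites$mid[which_hit[, 1]] - config$span %/% 2 +
          (which_hit[, 2] - 1L) * config$bin
        peaks <- tibble(
          chrom = sites$chrom[which_hit[, 1]],
          start = pmax(0, b_start + 5),
          end = b_start + config$bin - 5
        )
        peaks <- peaks[peaks$end > peaks$start, , drop = FALSE]
        peaks <- arrange(peaks, .data$chrom, .data$start)
        write_narrowpeak_file(peaks, file.path(samples$dir[i],
                                               paste0(tr, ".narrowPeak")))
      }
    }
    invisible(list(dir = out_dir, samples = samples, sites = sites,
                   config = config))
  })
}

# -- format writers (inverse of the genomic_io readers) ----------------------

write_narrowpeak_file <- function(peaks, path) {
  peaks <- as_tibble(peaks)
  out <- tibble(
    chrom = peaks$chrom,
    start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = 0L,
    strand = ".",
    signal = if ("score" %in% names(peaks) && !is.null(peaks$score)) {
      fmt_num(peaks$score, 3)
    } else fmt_num(runif(nrow(peaks), 2, 20), 3),
    p = -1, q = -1,
    peak = as.integer(floor((peaks$end - peaks$start) / 2))
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

write_fimo_file <- function(motifs, path) {
  out <- tibble(
    motif_id = "MA0139.1", motif_alt_id = "CTCF",
    sequence_name = motifs$chrom,
    start = as.integer(motifs$start) + 1L,  # FIMO is 1-based inclusive
    stop = as.integer(motifs$end),
    strand = motifs$strand,
    score = fmt_num(motifs$score, 4),
    `p-value` = format(motifs$p_value, scientific = TRUE),
    `q-value` = "", matched_sequence = ""
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

write_bedpe_file <- function(loops, path) {
  out <- tibble(
    chrom1 = loops$chrom, start1 = loops$start1, end1 = loops$end1,
    chrom2 = loops$chrom, start2 = loops$start2, end2 = loops$end2,
    pet = loops$pet_count, p = fmt_num(loops$fdr / 2, 4),
    fdr = fmt_num(loops$fdr, 4)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

write_gtf_file <- function(genes, path) {
  attrs <- sprintf('gene_id "%s"; gene_name "%s";',
                   genes$gene_id, genes$gene_name)
  lines <- paste(genes$chrom, "synthetic", "gene",
                 genes$start + 1L, genes$end, ".", genes$strand, ".",
                 attrs, sep = "\t")
  readr::write_lines(c("##provider: synthetic fixture", lines), path)
  invisible(path)
}
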