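#' Tracks used by the binding predictor under each preset
#'
#' @param preset `"cellline"` (accessibility, h3k4me1, h3k9me3, h3k27me3,
#'   h3k27ac, methylation) or `"ad"` (accessibility, h3k4me3, h3k27me3,
#'   h3k27ac).
#' @return Character vector of track names.
#' @export
binding_preset_tracks <- function(preset = c("cellline", "ad")) {
  switch(match.arg(preset),
    cellline = c("dnase", "h3k4me1", "h3k9me3", "h3k27me3", "h3k27ac",
                 "methylation"),
    ad = c("dnase", "h3k4me3", "h3k27me3", "h3k27ac")
  )
}

#' Build binned epigenomic matrices around candidate binding sites
#'
#' Each motif site gets a `span`-bp region centred on its midpoint, tiled
#' by consecutive `bin`-bp bins (20 bins of 25 bp by default). Every
#' (track, bin) cell is a 0/1 flag: 1 iff any track interval overlaps the
#' bin. Bins that would extend past the chromosome start are clamped out
#' and flagged 0. The FIMO motif score is carried as an extra feature.
#'
#' @param sites Motif tibble from [read_fimo_tsv()].
#' @param tracks Named list of peak tibbles / `interval_index` objects,
#'   one per configured track.
#' @param track_names Tracks to use (default: all of `tracks`); each must
#'   be present in `tracks`.
#' @param span,bin Region width and bin width in bp; `span` must be
#'   divisible by `bin`.
#' @return A tibble: `site_id`, `fimo_score`, then
#'   `<track>_bin01 ... <track>_binNN` flag columns; schema in
#'   `attr(x, "schema")`.
#' @export
build_site_matrices <- function(sites, tracks, track_names = names(tracks),
                                span = 500, bin = 25) {
  if (span %% bin != 0) abort("`span` must be divisible by `bin`.")
  missing <- setdiff(track_names, names(tracks))
  if (length(missing) > 0) {
    abort(sprintf("Track(s) missing: %s.", paste(missing, collapse = ", ")))
  }
  n_bins <- span %/% bin
  mid <- floor((sites$start + sites$end) / 2)
  out <- tibble(site_id = site_key(sites), fimo_score = sites$score)
  for (tr in track_names) {
    idx <- as_index(tracks[[tr]])
    for (b in seq_len(n_bins)) {
      b_start <- mid - span %/% 2 + (b - 1L) * bin
      b_end <- b_start + bin
      off <- b_end <= 0                       # bin entirely before chrom start
      q <- tibble(chrom = sites$chrom,
                  start = ifelse(off, 0L, pmax(0L, b_start)),
                  end = ifelse(off, 1L, b_end))
      flag <- idx_any_overlap(idx, q)
      flag[off] <- FALSE
      out[[sprintf("%s_bin%02d", tr, b)]] <- as.numeric(flag)
    }
  }
  attr(out, "schema") <- setdiff(names(out), "site_id")
  out
}

#' Label candidate binding sites by CTCF ChIP-seq occupancy
#'
#' @param sites Motif tibble.
#' @param ctcf_peaks CTCF peak tibble or `interval_index`.
#' @return Character vector `"bound"`/`"unbound"`: bound iff the motif
#'   interval overlaps a peak by >= 1 bp.
#' @export
label_sites <- function(sites, ctcf_peaks) {
  idx <- as_index(ctcf_peaks)
  ifelse(idx_any_overlap(idx, sites), "bound", "unbound")
}

#' Train the random-forest CTCF-binding predictor
#'
#' A probability forest (500 trees, sqrt-features per split) over the
#' binned track matrix. Single-threaded and seeded, so repeated fits are
#' identical.
#'
#' @param matrices Site-matrix tibble from [build_site_matrices()].
#' @param labels `"bound"`/`"unbound"` vector (or logical/0-1).
#' @param num_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return An object of class `binding_model`.
#' @export
train_binding_model <- function(matrices, labels, num_trees = 500, seed = 1) {
  x <- binding_matrix(matrices)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) abort("Training labels contain a single class.")
  df <- as.data.frame(x)
  df$.label <- factor(ifelse(y == 1, "bound", "unbound"),
                      levels = c("unbound", "bound"))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df, probability = TRUE,
    num.trees = num_trees, mtry = floor(sqrt(ncol(x))),
    importance = "impurity", seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance
  imp <- imp / sum(imp)
  structure(
    list(forest = fit, schema = colnames(x),
         hyperparams = list(num_trees = num_trees,
                            mtry = floor(sqrt(ncol(x)))),
         seed = seed,
         importance = tibble(feature = names(imp),
                             importance = unname(imp)) |>
           arrange(desc(.data$importance))),
    class = "binding_model"
  )
}

#' Predict CTCF-binding probabilities
#'
#' @param model A `binding_model`.
#' @param matrices Site-matrix tibble with the model's schema.
#' @return Numeric vector of binding probabilities in input order.
#' @export
predict_binding <- function(model, matrices) {
  stopifnot(inherits(model, "binding_model"))
  x <- binding_matrix(matrices)
  check_schema(colnames(x), model$schema)
  if (nrow(x) == 0) return(numeric(0))
  df <- as.data.frame(x[, model$schema, drop = FALSE])
  as.numeric(predict(model$forest, data = df,
                     num.threads = 1)$predictions[, "bound"])
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("<binding_model: ranger, %d features, %d trees, seed %d>\n",
              length(x$schema), x$hyperparams$num_trees, x$seed))
  invisible(x)
}

#' @method tidy binding_model
#' @export
tidy.binding_model <- function(x, ...) x$importance

#' @method glance binding_model
#' @export
glance.binding_model <- function(x, ...) {
  tibble(n_features = length(x$schema),
         num_trees = x$hyperparams$num_trees,
         mtry = x$hyperparams$mtry, seed = x$seed)
}

binding_matrix <- function(matrices) {
  x <- as_tibble(matrices)
  x <- x[, setdiff(names(x), c("site_id", "label")), drop = FALSE]
  as.matrix(x)
}

site_key <- function(sites) {
  paste(sites$chrom, sites$start, sites$end, sep = ":")
}
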