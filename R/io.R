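# On-disk containers and benchmark-layout reader. Containers are serialized
# with saveRDS (bit-exact round trip) and embed the package version and an
# md5 provenance hash.

container_header <- function(format, payload) {
  list(format = format, container_version = 1L,
       package_version = as.character(utils::packageVersion("adtrca")),
       config_hash = hash_object(payload))
}

#' Write / read the epoched-trials container
#'
#' Bit-exact round-tripping serialization of an [epoched_trials()] object,
#' with embedded package version and content hash.
#'
#' @param trials an [epoched_trials()] object.
#' @param path destination / source file.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "epoched_trials"))
  obj <- c(container_header("adtrca-trials", unclass(trials)),
           list(trials = trials))
  saveRDS(obj, path, version = 2)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "adtrca-trials"))
    stop("not an adtrca trials container: ", path)
  obj$trials
}

#' Write / read a fitted model bank
#'
#' @param bank a `filter_bank` from [trca_fit()] or [adtrca_fit()].
#' @param path destination / source file.
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "filter_bank"))
  obj <- c(container_header("adtrca-bank", unclass(bank)),
           list(bank = bank))
  saveRDS(obj, path, version = 2)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "adtrca-bank"))
    stop("not an adtrca model container: ", path)
  obj$bank
}

#' The 9 occipital-parietal channels of the 40-target benchmark montage
#' @export
speller_occipital_channels <- function()
  c("Pz", "PO5", "PO3", "POz", "PO4", "PO6", "O1", "Oz", "O2")

#' The 5 "hairless" (prefrontal/near-ear) channels of the same montage
#' @export
speller_hairless_channels <- function()
  c("FP1", "FPz", "FP2", "TP7", "TP8")

#' Layout description for a benchmark-style 4-D tensor
#'
#' The public 40-target benchmark stores one array per subject with
#' dimensions (channel, sample, target, block). This object names the
#' dimension order, the channel names and the sampling rate so the tensor
#' can be unrolled into [epoched_trials()].
#'
#' @param dims character vector naming the four dimensions; a permutation
#'   of `c("channel", "sample", "target", "block")`.
#' @param channel_names channel names along the channel dimension.
#' @param sampling_rate sampling rate in Hz.
#' @export
benchmark_layout <- function(dims = c("channel", "sample", "target",
                                      "block"),
                             channel_names, sampling_rate) {
  if (!setequal(dims, c("channel", "sample", "target", "block")))
    stop("dims must be a permutation of channel/sample/target/block")
  list(dims = dims, channel_names = channel_names,
       sampling_rate = sampling_rate)
}

#' Unroll a benchmark-style 4-D tensor into epoched trials
#'
#' Accepts the per-subject array directly or a path to an `.rds` file
#' containing it (MATLAB source files are converted once outside the
#' package). Trials are unrolled block-major with labels = target index and
#' blocks = block index; channels can be restricted by name (e.g. the
#' occipital 9 or the hairless 5).
#'
#' @param x 4-D numeric array or path to an `.rds` file holding one.
#' @param layout a [benchmark_layout()].
#' @param channels optional channel-name (or index) subset.
#' @return an [epoched_trials()] object.
#' @export
read_benchmark_tensor <- function(x, layout, channels = NULL) {
  if (is.character(x)) x <- readRDS(x)
  if (!is.array(x) || length(dim(x)) != 4)
    stop("expected a 4-D array (channel x sample x target x block)")
  perm <- match(c("channel", "sample", "target", "block"), layout$dims)
  x <- aperm(x, perm)
  d <- dim(x)
  if (length(layout$channel_names) != d[1])
    stop(sprintf("layout declares %d channels but array has %d",
                 length(layout$channel_names), d[1]))
  n_tr <- d[3] * d[4]
  data <- array(0, c(n_tr, d[1], d[2]))
  labels <- integer(n_tr); blocks <- integer(n_tr)
  m <- 0
  for (b in seq_len(d[4])) for (s in seq_len(d[3])) {
    m <- m + 1
    data[m, , ] <- x[, , s, b]
    labels[m] <- s; blocks[m] <- b
  }
  out <- epoched_trials(data, labels, blocks, layout$sampling_rate,
                        layout$channel_names)
  if (!is.null(channels)) out <- select_channels(out, channels)
  out
}

#' Write a results table as delimited text
#'
#' Tab-separated table preceded by `#`-comment provenance lines (package
#' version and content hash).
#'
#' @param results a data.frame (e.g. from [experiment_grid()]).
#' @param path destination file.
#' @export
write_results_table <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# adtrca %s", utils::packageVersion("adtrca")), con)
  writeLines(sprintf("# content-hash %s", hash_object(results)), con)
  utils::write.table(results, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
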