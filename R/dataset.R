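# Synthetic training-set generation: N valid samples, each with one random
# attachment region and F independent force manipulations, solved with the
# Neo-Hookean FE model, filtered for numerical stability (Newton convergence
# and a 0.3 m cap on the largest nodal displacement), reduced to partial
# visible surfaces and encoded on the grid.

#' Generate a synthetic attachment-estimation dataset
#'
#' Repeats until exactly \code{n_samples} valid samples are stored: draws an
#' attachment region (5-50 percent of surface nodes), applies \code{frames}
#' random force manipulations (distinct patches and magnitudes), solves each
#' with Newton-Raphson and rejects the whole sample if any solve fails to
#' converge or exceeds \code{max_disp} of nodal displacement. Valid frames
#' are reduced to partial visible surfaces under a fixed virtual camera and
#' encoded as distance fields plus the attachment mask.
#'
#' @param model a \code{hex_model}.
#' @param n_samples number of valid samples to store.
#' @param frames F, deformed views per sample (shared attachment).
#' @param mat a \code{material} (default liver-like Neo-Hookean).
#' @param seed master RNG seed for the dataset.
#' @param coverage_range attachment coverage range (fraction of surface).
#' @param magnitude_range total patch force range in Newton.
#' @param visible_range visible-surface coverage range.
#' @param view_dir fixed virtual camera direction.
#' @param max_disp stability cap on the max nodal displacement norm (m).
#' @param solver_args list of arguments passed to \code{\link{solve_static}}.
#' @param keep_displacements store full nodal displacement fields per frame
#'   (needed for replay checks and legacy encodings; default TRUE).
#' @return object of class \code{attachment_dataset}: list with
#'   \code{samples} (each with \code{df}, \code{mask}, \code{attachment},
#'   \code{frames} metadata), \code{frames}, \code{grid}, \code{config} and
#'   \code{rejections} (counts by reason).
#' @export
generate_dataset <- function(model, n_samples, frames = 3L,
                             mat = material(), seed = 1L,
                             coverage_range = c(0.05, 0.50),
                             magnitude_range = c(0.1, 20),
                             visible_range = c(0.10, 1.00),
                             view_dir = c(0, 0, -1),
                             max_disp = 0.3,
                             solver_args = list(n_steps = 1L,
                                                max_halvings = 2L,
                                                max_total_iter = 35L),
                             keep_displacements = TRUE) {
  stopifnot(inherits(model, "hex_model"), n_samples >= 1, frames >= 1)
  config <- list(n_samples = n_samples, frames = frames, seed = seed,
                 coverage_range = coverage_range,
                 magnitude_range = magnitude_range,
                 visible_range = visible_range, view_dir = view_dir,
                 max_disp = max_disp, material = unclass(mat)[c("E", "nu")])
  samples <- vector("list", n_samples)
  rejections <- c(non_converged = 0L, displacement_cap = 0L)
  window <- integer(0)  # 1 = rejected, sliding 100-attempt window
  with_seed(substream_seed(seed, "dataset"), {
    stored <- 0L
    while (stored < n_samples) {
      s <- simulate_sample(model, frames, mat, coverage_range,
                           magnitude_range, visible_range, view_dir,
                           max_disp, solver_args)
      if (is.character(s)) {
        rejections[s] <- rejections[s] + 1L
        window <- c(window, 1L)
      } else {
        window <- c(window, 0L)
        stored <- stored + 1L
        enc <- encode_sample(s, model)
        if (!keep_displacements)
          s$frames <- lapply(s$frames, function(fr) { fr$displacements <- NULL; fr })
        samples[[stored]] <- c(enc, list(attachment = s$attachment,
                                         frames_meta = s$frames))
      }
      if (length(window) > 100L) window <- window[-1]
      if (length(window) == 100L && sum(window) > 95L)
        stop("dataset generation aborted: rejection rate above 95% over the ",
             "last 100 attempts (forces too large for the material/mesh?)")
      # sparse factors hold native memory invisible to R's heap accounting;
      # collect periodically so long generation runs stay flat
      if (stored %% 10L == 0L) gc(FALSE)
    }
  })
  ds <- list(samples = samples, frames = frames, grid = model$grid,
             dims = model$grid$dims, config = config,
             rejections = rejections)
  class(ds) <- "attachment_dataset"
  ds
}

# one sample attempt; returns a rejection reason string or the sample
simulate_sample <- function(model, frames, mat, coverage_range,
                            magnitude_range, visible_range, view_dir,
                            max_disp, solver_args) {
  attachment <- sample_attachment(model, coverage_range)
  forces <- list()
  out_frames <- vector("list", frames)
  for (f in seq_len(frames)) {
    repeat {
      force <- sample_force(model, attachment,
                            magnitude_range = magnitude_range)
      distinct <- all(vapply(forces, function(prev) {
        !identical(prev$patch_nodes, force$patch_nodes) &&
          prev$magnitude != force$magnitude
      }, logical(1)))
      if (distinct) break
    }
    forces[[f]] <- force
    res <- do.call(solve_static,
                   c(list(model, mat, force_bcs(attachment, force)),
                     solver_args))
    if (!res$converged) return("non_converged")
    if (max(sqrt(rowSums(res$displacements^2))) > max_disp)
      return("displacement_cap")
    vis <- extract_visible_surface(model, res$displacements,
                                   view_dir = view_dir,
                                   coverage_range = visible_range)
    out_frames[[f]] <- list(force = force, displacements = res$displacements,
                            visible_nodes = vis$nodes,
                            visible_coverage = vis$coverage,
                            iterations = res$iterations)
  }
  list(attachment = attachment, frames = out_frames)
}

#' @export
print.attachment_dataset <- function(x, ...) {
  cat(sprintf("attachment_dataset: %d samples, F = %d frames, grid %s\n",
              length(x$samples), x$frames,
              paste(x$dims, collapse = " x ")))
  cat(sprintf("  rejections: %d non-converged, %d over displacement cap\n",
              x$rejections["non_converged"], x$rejections["displacement_cap"]))
  invisible(x)
}

#' Save / load a dataset
#'
#' Serialized with \code{saveRDS}; a fixed generation seed yields an
#' identical file.
#'
#' @param dataset an \code{attachment_dataset}.
#' @param path file path (.rds).
#' @export
save_dataset <- function(dataset, path) {
  saveRDS(dataset, path, version = 3)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)
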