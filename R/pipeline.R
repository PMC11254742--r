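# End-to-end pipeline: simulate (or load) -> segment -> stitch -> coarse
# register -> fine register & link -> read intensities -> call bases ->
# census, with a run report and optional on-disk outputs.

#' Run the full puck-processing pipeline
#'
#' Processes a complete acquisition: detects beads on every brightfield
#' tile, stitches each round's tiles into a mosaic, rigidly registers every
#' round onto round 1, links beads across rounds patch-by-patch under the
#' congruence rule, reads the per-round fluorescence gray values at the
#' linked positions, calls bases with the trained network, assembles
#' barcodes and tabulates the patch change census.
#'
#' @param input either a [simulation_config()] (the acquisition is generated
#'   in memory with ground truth) or a list of `tile_stack`s from
#'   [read_acquisition()].
#' @param spec an [acquisition_spec()]; defaults to the simulation config's.
#' @param segment_method `"oracle"` (classical detector, default) or
#'   `"cnn"` (trains the small segmentation network on round-1 labels; with
#'   simulated input the labels come from ground truth).
#' @param seg_config a [segmenter_config()].
#' @param coarse_config a [coarse_reg_config()].
#' @param fine_config a [fine_reg_config()].
#' @param caller either a trained `base_caller`, or a [base_caller_config()]
#'   used to train one on `n_caller_samples` simulated intensity vectors
#'   (requires a simulation config input).
#' @param n_caller_samples,n_caller_train samples / training split for the
#'   caller when it is trained in-run.
#' @param stitch_radius stitch search half-width (px).
#' @param out_dir if given, outputs (barcodes TSV, layouts and transforms
#'   JSON, census CSV, report JSON) are written there.
#' @param verbose print stage progress.
#' @return object of class `puck_run`: list with `barcodes`
#'   (a [barcode_table()]), `tracks`, `transforms`, `layouts`, `round_beads`,
#'   `census`, `report`, `caller` and (simulated input) `truth`.
#' @export
run_pipeline <- function(input, spec = NULL,
                         segment_method = c("oracle", "cnn"),
                         seg_config = segmenter_config(),
                         coarse_config = coarse_reg_config(),
                         fine_config = fine_reg_config(),
                         caller = base_caller_config(),
                         n_caller_samples = 1746L, n_caller_train = 1575L,
                         stitch_radius = 15L, out_dir = NULL, verbose = FALSE) {
  segment_method <- match.arg(segment_method)
  say <- function(...) if (verbose) message(sprintf(...))

  truth <- NULL
  if (inherits(input, "simulation_config")) {
    say("simulating acquisition (%d rounds, %d beads)",
        input$acquisition$n_sequences, input$n_beads)
    acq <- generate_acquisition(input)
    truth <- acq$truth
    stacks <- acq$stacks
    if (is.null(spec)) spec <- input$acquisition
  } else {
    stacks <- input
    if (is.null(spec)) stop("spec must be given when input is a tile-stack list")
  }
  R <- length(stacks)

  seg_model <- NULL
  if (segment_method == "cnn") {
    if (is.null(truth))
      stop("segment_method='cnn' needs simulated input (labels) or a pre-trained model")
    say("training segmentation network on round-1 labels")
    lay <- nominal_layout(spec)
    p1 <- truth_positions_round(truth, 1L)   # anchored at tile 1's origin
    imgs <- list(); msks <- list()
    for (k in seq_len(min(2L, n_tiles(spec)))) {
      o <- truth$tile_offsets[[1]][k, ] - truth$tile_offsets[[1]][1, ]
      loc <- cbind(p1[, 1] - o[["dx"]], p1[, 2] - o[["dy"]])
      keep <- loc[, 1] >= 0 & loc[, 1] < spec$tile_size &
              loc[, 2] >= 0 & loc[, 2] < spec$tile_size
      imgs[[k]] <- stacks[[1]]$images[[k]][["brightfield"]]
      msks[[k]] <- segmentation_labels(loc[keep, , drop = FALSE],
                                       if (inherits(input, "simulation_config"))
                                         input$bead_radius else 5,
                                       c(spec$tile_size, spec$tile_size))
    }
    seg_model <- train_segmenter(imgs, msks, seg_config)
  }

  say("segmenting and stitching %d rounds", R)
  rounds <- vector("list", R)
  for (r in seq_len(R)) {
    rounds[[r]] <- stitch_round(stacks[[r]], spec, seg_config,
                                method = segment_method, model = seg_model,
                                search_radius = stitch_radius)
    say("  round %2d: %d beads", r, nrow(rounds[[r]]$beads))
  }
  round_beads <- lapply(rounds, `[[`, "beads")

  say("coarse registration onto round 1")
  transforms <- vector("list", R)
  transforms[[1]] <- rigid_transform(0, 0, 0, c(0, 0))
  reg_cost <- data.frame(round = seq_len(R), cost_before = NA_real_,
                         cost_after = NA_real_)
  for (r in seq_len(R)[-1]) {
    reg <- register_round(round_beads[[1]], round_beads[[r]], coarse_config,
                          circle_radius = seg_config$circle_radius)
    transforms[[r]] <- reg$transform
    reg_cost$cost_before[r] <- reg$cost_before
    reg_cost$cost_after[r] <- reg$cost
  }

  say("fine registration and cross-round linking")
  tracks <- link_across_sequences(round_beads[[1]], round_beads, transforms,
                                  fine_config)

  say("training / applying base caller")
  if (inherits(caller, "base_caller_config")) {
    if (inherits(input, "simulation_config")) {
      smp <- simulate_intensity_samples(n_caller_samples, input,
                                        seed = sub_seed(input$seed, "caller"))
      caller <- train_base_caller(smp$samples, smp$labels, caller,
                                  n_train = n_caller_train)
    } else {
      stop("supply a trained base_caller when running on loaded data")
    }
  }

  say("reading fluorescence intensities")
  fluor <- lapply(seq_len(R), function(r) {
    mos <- lapply(FLUOR_CHANNELS, function(ch)
      compose_mosaic(lapply(stacks[[r]]$images, `[[`, ch),
                     rounds[[r]]$layout, mode = "mean"))
    names(mos) <- FLUOR_CHANNELS
    org <- rounds[[r]]$layout$origin
    if (!is.null(org)) for (ch in FLUOR_CHANNELS) attr(mos[[ch]], "origin") <- org
    mos
  })
  intens <- read_bead_intensities(tracks, round_beads, fluor,
                                  radius = seg_config$circle_radius)
  barcodes <- assemble_barcodes(tracks, intens, caller)

  say("patch census")
  reg_beads <- lapply(seq_len(R), function(r) {
    b <- round_beads[[r]]
    if (r == 1L || nrow(b) == 0L) return(b)
    apply_rigid(b, transforms[[r]])
  })
  mosaic_shape <- rounds[[1]]$layout$mosaic_shape
  census <- patch_census(reg_beads, patch_size = 50L,
                         circle_radius = seg_config$circle_radius,
                         mosaic_shape = mosaic_shape)

  mc <- grep("^match_r", names(tracks))
  matched_all <- rowSums(!is.na(as.data.frame(tracks)[mc])) == length(mc)
  report <- list(
    n_rounds = R,
    beads_per_round = vapply(round_beads, nrow, integer(1)),
    n_reference_beads = nrow(tracks),
    match_rate_all_rounds = mean(matched_all),
    mean_completeness = mean(barcodes$completeness),
    registration = reg_cost)

  out <- structure(list(barcodes = barcodes, tracks = tracks,
                        transforms = transforms,
                        layouts = lapply(rounds, `[[`, "layout"),
                        round_beads = round_beads, census = census,
                        report = report, caller = caller, truth = truth,
                        seg_model = seg_model),
                   class = "puck_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.puck_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("Puck run: %d rounds, %d reference beads\n", r$n_rounds,
              r$n_reference_beads))
  cat(sprintf("  tracked in all rounds: %.1f%%\n", 100 * r$match_rate_all_rounds))
  cat(sprintf("  mean barcode completeness: %.3f\n", r$mean_completeness))
  if (!is.null(x$audit))
    cat(sprintf("  ground-truth audit: %.1f%% correct across all rounds\n",
                100 * x$audit$fraction_correct))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits `barcodes.tsv`, `layouts.json`, `transforms.json`, `census.csv` and
#' `report.json`.
#'
#' @param run a `puck_run`.
#' @param dir output directory (created).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_barcode_table(run$barcodes, file.path(dir, "barcodes.tsv"))
  lay <- lapply(run$layouts, function(l)
    list(offsets = l$offsets, mosaic_shape = l$mosaic_shape))
  jsonlite::write_json(lay, file.path(dir, "layouts.json"), auto_unbox = TRUE,
                       digits = NA)
  tr <- lapply(run$transforms, function(t)
    list(theta_deg = t$theta * 180 / pi, tx = t$tx, ty = t$ty,
         pivot = t$center))
  jsonlite::write_json(tr, file.path(dir, "transforms.json"),
                       auto_unbox = TRUE, digits = NA)
  write_census(run$census, file.path(dir, "census.csv"))
  rep <- run$report
  rep$beads_per_round <- as.list(rep$beads_per_round)
  jsonlite::write_json(rep, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(dir)
}

#' Audit pipeline tracks against simulator ground truth
#'
#' Maps every round's detections to ground-truth beads by nearest neighbour
#' (one-to-one, within `audit_radius`), then checks, for each ground-truth
#' bead present in all rounds, whether the pipeline linked detections of that
#' same bead in every round.  This mirrors a manual audit of bead identity
#' across sequences.
#'
#' @param run a `puck_run` produced from a simulation config.
#' @param audit_radius detection-to-truth association radius (px); beads are
#'   separated by far more than this, so identity is unambiguous.
#' @param max_beads audit at most this many beads (all by default).
#' @return list with `n_audited`, `n_correct`, `fraction_correct` and the
#'   per-round correct counts.
#' @export
audit_tracks <- function(run, audit_radius = 5, max_beads = Inf) {
  truth <- run$truth
  if (is.null(truth)) stop("run has no ground truth to audit against")
  R <- length(run$round_beads)
  # detection id -> ground-truth id per round
  det2gt <- vector("list", R)
  for (r in seq_len(R)) {
    gt <- truth_positions_round(truth, r)
    det <- run$round_beads[[r]]
    m <- match_points(bead_xy(det), gt, threshold = audit_radius)
    map <- rep(NA_integer_, max(det$id, 0L))
    if (nrow(m$pairs)) map[det$id[m$pairs$ref]] <- attr(gt, "gt_id")[m$pairs$mov]
    det2gt[[r]] <- map
  }
  present_all <- which(rowSums(truth$present) == ncol(truth$present))
  if (length(present_all) > max_beads)
    present_all <- present_all[seq_len(max_beads)]
  tracks <- run$tracks
  mc <- paste0("match_r", seq_len(R))
  ref_gt <- det2gt[[1]][tracks$bead_id]
  row_of_gt <- match(present_all, ref_gt)
  per_round_correct <- integer(R)
  n_correct <- 0L
  for (k in seq_along(present_all)) {
    g <- present_all[k]; row <- row_of_gt[k]
    if (is.na(row)) next                      # bead never picked up in round 1
    ok_all <- TRUE
    for (r in seq_len(R)) {
      id_r <- tracks[[mc[r]]][row]
      ok <- !is.na(id_r) && !is.na(det2gt[[r]][id_r]) && det2gt[[r]][id_r] == g
      if (ok) per_round_correct[r] <- per_round_correct[r] + 1L else ok_all <- FALSE
    }
    if (ok_all) n_correct <- n_correct + 1L
  }
  list(n_audited = length(present_all), n_correct = n_correct,
       fraction_correct = n_correct / length(present_all),
       per_round_correct = per_round_correct)
}

#' Fraction of ground-truth beads whose called barcode equals the truth
#'
#' Ground-truth-centric: for each simulated bead present in all rounds, the
#' nearest reference detection (one-to-one, within `audit_radius`) must carry
#' a fully called barcode identical to the bead's true barcode.
#'
#' @param run a `puck_run` with ground truth.
#' @param audit_radius detection-to-truth association radius (px).
#' @return list with `n_beads` (ground-truth beads present in all rounds),
#'   `n_exact` and `fraction_exact`.
#' @export
barcode_accuracy <- function(run, audit_radius = 5) {
  truth <- run$truth
  if (is.null(truth)) stop("run has no ground truth")
  gt1 <- truth_positions_round(truth, 1L)
  det <- run$round_beads[[1]]
  m <- match_points(gt1, bead_xy(det), threshold = audit_radius)
  gt2det <- rep(NA_integer_, nrow(truth$positions))
  if (nrow(m$pairs)) gt2det[attr(gt1, "gt_id")[m$pairs$ref]] <- det$id[m$pairs$mov]
  present_all <- which(rowSums(truth$present) == ncol(truth$present))
  truth_bc <- apply(truth$barcodes, 1, paste0, collapse = "")
  bc <- run$barcodes
  row_of_det <- match(gt2det[present_all], bc$bead_id)
  ok <- !is.na(row_of_det) &
    bc$barcode[row_of_det] == truth_bc[present_all] &
    bc$completeness[row_of_det] == 1
  ok[is.na(ok)] <- FALSE
  list(n_beads = length(present_all), n_exact = sum(ok),
       fraction_exact = if (length(present_all)) mean(ok) else NA_real_)
}
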