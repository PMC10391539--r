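# End-to-end orchestration: train the stage-1 dense U-net on full slices,
# build the stage-2 crop dataset from label trachea centroids, train the
# stage-2 residual attention network on 64x64 crops, run two-step inference
# (stage-1 labels -> predicted trachea centroid -> crop -> stage-2 esophagus
# -> paste-back), evaluate cohorts and compare models. Training is slice-wise
# (2-D) with batch size 1 and fully seeded.

stage1_organs <- function() c("left_lung", "right_lung", "heart", "cord", "trachea")

#' Split a generated cohort into train/val/test sets
#'
#' @param cohort Named list of `phantom_sample`s.
#' @param split Named sizes, e.g. `c(train = 39, val = 8, test = 12)`.
#' @return List of per-split lists of samples; patient-disjoint by
#'   construction.
#' @export
split_cohort <- function(cohort, split = c(train = 39L, val = 8L, test = 12L)) {
  if (sum(split) != length(cohort))
    ts_error("split sizes must sum to the cohort size", "ts_validation_error")
  idx <- split(seq_along(cohort), rep(names(split), times = split)[seq_along(cohort)])
  out <- lapply(names(split), function(s) cohort[idx[[s]]])
  names(out) <- names(split)
  assert_split_integrity(out)
  out
}

#' Assert that no patient appears in two splits
#' @param data Named list of splits, each a named list of samples.
#' @return Invisibly `TRUE`; errors on overlap.
#' @export
assert_split_integrity <- function(data) {
  ids <- lapply(data, names)
  all_ids <- unlist(ids)
  if (anyDuplicated(all_ids))
    ts_error(sprintf("patient ids in multiple splits: %s",
                     paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")),
             "ts_validation_error")
  invisible(TRUE)
}

#' Read a dataset directory written by [write_cohort]
#'
#' @param dir Directory with `<split>/<patient_id>/ct.nii.gz` +
#'   `labels.nii.gz`.
#' @return Named list of splits, each a named list of
#'   `list(ct, labels)` samples.
#' @export
load_dataset <- function(dir) {
  splits <- intersect(c("train", "val", "test"), list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (!length(splits)) ts_error("no split subdirectories found", "ts_data_error")
  out <- lapply(splits, function(s) {
    pats <- list.dirs(file.path(dir, s), recursive = FALSE, full.names = FALSE)
    ps <- lapply(pats, function(p) {
      list(ct = read_volume(file.path(dir, s, p, "ct.nii.gz")),
           labels = read_labelmap(file.path(dir, s, p, "labels.nii.gz")))
    })
    names(ps) <- pats
    ps
  })
  names(out) <- splits
  assert_split_integrity(out)
  out
}

#' Training configuration
#'
#' @param net A [network_config].
#' @param epochs Passes over the training slices.
#' @param lr Adam learning rate.
#' @param dice_weight Weight of the soft-Dice term in the loss (the rest is
#'   cross-entropy).
#' @param seed Seed for shuffling and crop jitter.
#' @param slices_per_patient Evenly spaced slice subsample per patient
#'   (`NULL` = all slices).
#' @param val_slices_per_patient Slices per validation patient used for the
#'   per-epoch validation score.
#' @return A `train_config` list.
#' @export
train_config <- function(net, epochs = 2L, lr = 1e-3, dice_weight = 0.5,
                         seed = 1L, slices_per_patient = NULL,
                         val_slices_per_patient = 2L) {
  stopifnot(inherits(net, "network_config"))
  structure(list(net = net, epochs = as.integer(epochs), lr = lr,
                 dice_weight = dice_weight, seed = as.integer(seed),
                 slices_per_patient = slices_per_patient,
                 val_slices_per_patient = as.integer(val_slices_per_patient)),
            class = "train_config")
}

ct_to_unit_slices <- function(ct) {
  u <- to_unit_interval(apply_window(ct))
  u$voxels
}

pick_slices <- function(n_slices, k) {
  if (is.null(k) || k >= n_slices) seq_len(n_slices)
  else unique(as.integer(round(seq(1, n_slices, length.out = k))))
}

# flat per-slice training items for full-slice segmentation
slice_items <- function(samples, class_codes, slices_per_patient = NULL) {
  items <- list()
  for (pid in names(samples)) {
    s <- samples[[pid]]
    u <- ct_to_unit_slices(s$ct)
    for (i in pick_slices(dim(u)[1], slices_per_patient)) {
      y <- s$labels$labels[i, , ]
      y[!(y %in% class_codes)] <- 0L
      items[[length(items) + 1L]] <- list(x = u[i, , ], y = y, patient = pid, slice = i)
    }
  }
  items
}

onehot_codes <- function(y, class_codes) {
  H <- nrow(y); W <- ncol(y); C <- length(class_codes)
  t <- array(0, dim = c(H, W, C, 1L))
  for (k in seq_len(C)) t[, , k, 1L] <- (y == class_codes[k])
  t
}

argmax_classes <- function(logits) {
  d <- dim(logits); C <- d[3]
  m <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = C)
  array(max.col(m, ties.method = "first"), dim = c(d[1], d[2], d[4]))
}

# shared training loop; items yield (x matrix, y target), loss_type picks the
# head; val_fn(model) returns a scalar score tracked per epoch, with the best
# weights kept
train_loop <- function(model, items, cfg, loss_type = c("softmax", "sigmoid"),
                       class_codes = NULL, val_fn = NULL) {
  loss_type <- match.arg(loss_type)
  if (!length(items)) ts_error("empty training set", "ts_data_error")
  st <- adam_state(model$params)
  history <- data.frame(epoch = integer(), mean_loss = numeric(), val_score = numeric())
  best <- list(score = -Inf, weights = NULL)
  snapshot <- function() lapply(model$params, function(p) p$value)
  score0 <- if (!is.null(val_fn)) val_fn(model) else NA_real_
  history <- rbind(history, data.frame(epoch = 0L, mean_loss = NA_real_, val_score = score0))
  if (!is.null(val_fn)) best <- list(score = score0, weights = snapshot())
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(items))
      losses <- numeric(length(ord))
      for (j in seq_along(ord)) {
        it <- items[[ord[j]]]
        x <- ad_input(fm4(it$x))
        logits <- model$forward(x)
        loss <- if (loss_type == "softmax")
          loss_softmax_ce_dice(logits, onehot_codes(it$y, class_codes), cfg$dice_weight)
        else
          loss_sigmoid_bce_dice(logits, fm4(it$y * 1), cfg$dice_weight)
        if (!is.finite(loss$value))
          ts_error(sprintf("non-finite loss at epoch %d step %d", ep, j), "ts_train_error")
        ad_backward(loss)
        st <- adam_step(st, lr = cfg$lr)
        losses[j] <- loss$value
      }
      sc <- if (!is.null(val_fn)) val_fn(model) else NA_real_
      history <- rbind(history, data.frame(epoch = ep, mean_loss = mean(losses), val_score = sc))
      if (!is.null(val_fn) && sc >= best$score) best <- list(score = sc, weights = snapshot())
    }
  })
  if (!is.null(best$weights))
    for (nm in names(best$weights)) model$params[[nm]]$value <- best$weights[[nm]]
  list(model = model, history = history)
}

# cohort-level multi-organ DSC of argmax predictions on a slice subsample
val_dsc_fn <- function(samples, class_codes, k_slices) {
  items <- slice_items(samples, class_codes, k_slices)
  H <- nrow(items[[1L]]$x); W <- ncol(items[[1L]]$x)
  xb <- array(0, dim = c(H, W, 1L, length(items)))
  for (j in seq_along(items)) xb[, , 1L, j] <- items[[j]]$x
  function(model) {
    C <- length(class_codes)
    cls <- argmax_classes(model_forward(model, xb))
    inter <- tot <- numeric(C)
    for (j in seq_along(items)) {
      pred <- class_codes[cls[, , j]]
      for (k in 2:C) {  # skip background
        inter[k] <- inter[k] + sum(pred == class_codes[k] & items[[j]]$y == class_codes[k])
        tot[k] <- tot[k] + sum(pred == class_codes[k]) + sum(items[[j]]$y == class_codes[k])
      }
    }
    d <- ifelse(tot[2:C] > 0, 2 * inter[2:C] / tot[2:C], 1)
    mean(d)
  }
}

#' Train the stage-1 full-slice network
#'
#' Six-class by default (background + lungs, heart, cord, trachea); passing
#' `organs = c(stage1_organs(), "esophagus")` trains the 7-class variant
#' used only for the one-step ablation. The per-epoch validation score is
#' the cohort mean multi-organ DSC; the best-scoring weights are kept.
#'
#' @param data Named list with `train` and `val` splits of samples
#'   (`list(ct, labels)` each).
#' @param cfg A [train_config] whose `net$n_classes` must equal
#'   `length(organs) + 1`.
#' @param organs Organ names segmented by the network.
#' @return List with `model`, `history`, `organs`, `class_codes`.
#' @export
train_stage1 <- function(data, cfg, organs = stage1_organs()) {
  if (is.null(data$train) || !length(data$train)) ts_error("empty training split", "ts_data_error")
  if (is.null(data$val) || !length(data$val)) ts_error("missing validation split", "ts_config_error")
  assert_split_integrity(data)
  lt <- data$train[[1L]]$labels$label_table
  class_codes <- c(0L, unname(lt[organs]))
  if (cfg$net$n_classes != length(class_codes))
    ts_error("net n_classes must be length(organs) + 1", "ts_config_error")
  model <- build_network(cfg$net)
  fit <- train_loop(model, slice_items(data$train, class_codes, cfg$slices_per_patient),
                    cfg, "softmax", class_codes,
                    val_dsc_fn(data$val, class_codes, cfg$val_slices_per_patient))
  c(fit, list(organs = organs, class_codes = class_codes))
}

#' Build the stage-2 crop dataset
#'
#' For every slice of every patient: the label trachea centroid, jittered by
#' [training_center] (or the plain [inference_center] when `jitter = FALSE`,
#' as for validation crops), centers a crop of the windowed CT and of the
#' esophagus label. Slices whose trachea is empty chain from the previous
#' slice's center; crops that miss the esophagus are re-centered by the same
#' 1 mm fallback steps. Every emitted crop contains at least one esophagus
#' pixel; slices where that cannot be achieved are skipped and logged.
#'
#' @param samples Named list of `list(ct, labels)` samples.
#' @param spec A [crop_spec].
#' @param jitter Apply training-time random jitter.
#' @param seed Seed for the jitter.
#' @param max_fallback Maximum fallback steps per slice.
#' @param slices_per_patient Evenly spaced slice subsample (`NULL` = all).
#' @return List with `crops` (each `list(x, y, region, patient, slice)`)
#'   and `log` (character vector of skipped slices).
#' @export
build_stage2_dataset <- function(samples, spec = crop_spec(), jitter = TRUE,
                                 seed = 1L, max_fallback = 200L,
                                 slices_per_patient = NULL) {
  crops <- list(); logs <- character()
  with_seed(seed, {
    for (pid in names(samples)) {
      s <- samples[[pid]]
      u <- ct_to_unit_slices(s$ct)
      eso <- organ_mask(s$labels, "esophagus")
      tra <- organ_mask(s$labels, "trachea")
      sp <- s$labels$spacing[2:3]
      prev <- NULL
      for (i in pick_slices(dim(u)[1], slices_per_patient)) {
        tm <- tra[i, , ]
        if (any(tm)) {
          ctr <- centroid(tm)
          center <- if (jitter) training_center(ctr, sp, spec)
                    else inference_center(ctr, sp, spec)
        } else if (!is.null(prev)) {
          center <- fallback_center(prev, sp, spec)
        } else {
          logs <- c(logs, sprintf("%s slice %d: no trachea and no previous center", pid, i))
          next
        }
        em <- eso[i, , ]
        if (!any(em)) {
          logs <- c(logs, sprintf("%s slice %d: no esophagus label", pid, i))
          prev <- center
          next
        }
        got <- extract_crop(em * 1, center, spec, i)
        tries <- 0L
        while (!any(got$crop > 0) && tries < max_fallback) {
          center <- fallback_center(center, sp, spec)
          got <- extract_crop(em * 1, center, spec, i)
          tries <- tries + 1L
        }
        if (!any(got$crop > 0)) {
          logs <- c(logs, sprintf("%s slice %d: crop never reached the esophagus", pid, i))
          prev <- center
          next
        }
        xcrop <- extract_crop(u[i, , ], center, spec, i)
        crops[[length(crops) + 1L]] <- list(x = xcrop$crop, y = got$crop > 0,
                                            region = xcrop$region,
                                            patient = pid, slice = i)
        prev <- center
      }
    }
  })
  list(crops = crops, log = logs)
}

#' Train the stage-2 esophagus crop network
#'
#' Binary (esophagus vs background) on `crop_size` square crops; the
#' validation score is the pooled crop DSC at threshold 0.5.
#'
#' @param crop_data Output of [build_stage2_dataset] on the training split.
#' @param cfg A [train_config] with a 1-class sigmoid head.
#' @param val_crop_data Crops from the validation split (no jitter).
#' @param threshold Sigmoid decision threshold for the validation score.
#' @return List with `model` and `history`.
#' @export
train_stage2 <- function(crop_data, cfg, val_crop_data = NULL, threshold = 0.5) {
  items <- lapply(crop_data$crops, function(cr) list(x = cr$x, y = cr$y))
  if (!length(items)) ts_error("empty crop dataset", "ts_data_error")
  val_fn <- NULL
  if (!is.null(val_crop_data)) {
    vitems <- lapply(val_crop_data$crops, function(cr) list(x = cr$x, y = cr$y))
    val_fn <- function(model) {
      inter <- tot <- 0
      for (it in vitems) {
        p <- 1 / (1 + exp(-model_forward(model, it$x))) >= threshold
        inter <- inter + sum(p[, , 1, 1] & it$y)
        tot <- tot + sum(p) + sum(it$y)
      }
      if (tot > 0) 2 * inter / tot else 1
    }
  }
  train_loop(build_network(cfg$net), items, cfg, "sigmoid", val_fn = val_fn)
}

#' Stage-1 label prediction for a CT volume
#'
#' @param stage1 Result of [train_stage1] (or a compatible
#'   `list(model, organs, class_codes)`).
#' @param ct A [ct_volume] in HU.
#' @param label_table Label table for the output volume.
#' @return A [label_volume]; argmax ties go to the lowest class index.
#' @export
predict_stage1 <- function(stage1, ct, label_table = default_label_table()) {
  u <- ct_to_unit_slices(ct)
  d <- dim(u)
  xb <- array(aperm(u, c(2, 3, 1)), dim = c(d[2], d[3], 1L, d[1]))
  cls <- argmax_classes(model_forward(stage1$model, xb))
  lab <- array(0L, dim = d)
  for (i in seq_len(d[1])) lab[i, , ] <- stage1$class_codes[cls[, , i]]
  label_volume(lab, ct$spacing, label_table)
}

#' Two-step inference
#'
#' Stage-1 argmax labels give a per-slice predicted trachea centroid (with
#' fallback chaining over slices where the prediction is empty); the
#' inference center crops the windowed CT; the stage-2 network's sigmoid
#' output at `threshold` becomes the esophagus, pasted back over the
#' stage-1 labels. If no slice has a predicted trachea, the esophagus is
#' left empty volume-wide with a warning.
#'
#' @param ct A [ct_volume] in HU.
#' @param stage1 Result of [train_stage1] (6-class).
#' @param stage2 Result of [train_stage2].
#' @param spec A [crop_spec].
#' @param threshold Stage-2 decision threshold.
#' @param stage1_labels Optional [label_volume] used instead of the stage-1
#'   prediction (e.g. ground truth, to isolate stage-2 error).
#' @return A [label_volume] with all seven labels.
#' @export
infer_two_step <- function(ct, stage1, stage2, spec = crop_spec(), threshold = 0.5,
                           stage1_labels = NULL) {
  s1 <- if (is.null(stage1_labels)) predict_stage1(stage1, ct) else stage1_labels
  u <- ct_to_unit_slices(ct)
  sp <- ct$spacing[2:3]
  tra <- s1$labels == s1$label_table[["trachea"]]
  if (!any(tra)) {
    warning("no trachea predicted in any slice; esophagus left empty")
    lab <- s1$labels
    lab[lab == s1$label_table[["esophagus"]]] <- 0L
    return(label_volume(lab, s1$spacing, s1$label_table))
  }
  xcrops <- list(); regions <- list()
  prev <- NULL
  for (i in seq_len(dim(u)[1])) {
    tm <- tra[i, , ]
    if (any(tm)) {
      center <- inference_center(centroid(tm), sp, spec)
    } else if (!is.null(prev)) {
      center <- fallback_center(prev, sp, spec)
    } else {
      next
    }
    got <- extract_crop(u[i, , ], center, spec, i)
    xcrops[[length(xcrops) + 1L]] <- got$crop
    regions[[length(regions) + 1L]] <- got$region
    prev <- center
  }
  sz <- spec$crop_size
  xb <- array(0, dim = c(sz, sz, 1L, length(xcrops)))
  for (j in seq_along(xcrops)) xb[, , 1L, j] <- xcrops[[j]]
  p <- 1 / (1 + exp(-model_forward(stage2$model, xb)))
  crops <- lapply(seq_along(xcrops), function(j) p[, , 1L, j] >= threshold)
  paste_esophagus(s1, crops, regions)
}

#' Evaluate a cohort of predictions
#'
#' @param preds,gts Named lists of [label_volume]s with matching patient ids.
#' @param organs Organ names to score.
#' @return List of class `cohort_report`: `records` (per patient-organ
#'   data.frame) and `summary` (per organ-metric mean, sd, n over
#'   non-missing values).
#' @export
evaluate_cohort <- function(preds, gts, organs = names(gts[[1L]]$label_table)) {
  if (!setequal(names(preds), names(gts)))
    ts_error("prediction and ground-truth patient ids differ", "ts_validation_error")
  recs <- do.call(rbind, lapply(names(gts), function(pid)
    evaluate_patient(preds[[pid]], gts[[pid]], organs, patient_id = pid)))
  metrics <- c("dsc", "hd95_mm", "asd_mm")
  summ <- do.call(rbind, lapply(organs, function(o) {
    sub <- recs[recs$organ == o, ]
    do.call(rbind, lapply(metrics, function(m) {
      v <- sub[[m]][!is.na(sub[[m]])]
      data.frame(organ = o, metric = m,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  structure(list(records = recs, summary = summ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Paired comparison of two cohort reports
#'
#' Wilcoxon signed-rank test per organ-metric cell on patient-paired values
#' (exact distribution when at most 25 non-zero differences and no tied
#' ranks). All-zero differences give p = 1 by convention.
#'
#' @param reportA,reportB `cohort_report`s over the same patients.
#' @return data.frame organ, metric, mean_a, mean_b, p_value, n_pairs.
#' @export
compare_models <- function(reportA, reportB) {
  a <- reportA$records; b <- reportB$records
  if (!setequal(unique(a$patient_id), unique(b$patient_id)))
    ts_error("reports cover different patients", "ts_validation_error")
  metrics <- c("dsc", "hd95_mm", "asd_mm")
  out <- list()
  for (o in unique(a$organ)) {
    for (m in metrics) {
      sa <- a[a$organ == o, ]; sb <- b[b$organ == o, ]
      ids <- intersect(sa$patient_id, sb$patient_id)
      va <- sa[[m]][match(ids, sa$patient_id)]
      vb <- sb[[m]][match(ids, sb$patient_id)]
      ok <- !is.na(va) & !is.na(vb)
      va <- va[ok]; vb <- vb[ok]
      p <- NA_real_
      if (length(va)) {
        d <- va - vb
        if (all(d == 0)) {
          p <- 1
        } else {
          nz <- d[d != 0]
          exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
          p <- suppressWarnings(
            wilcox.test(va, vb, paired = TRUE, exact = exact)$p.value)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        organ = o, metric = m,
        mean_a = if (length(va)) mean(va) else NA_real_,
        mean_b = if (length(vb)) mean(vb) else NA_real_,
        p_value = p, n_pairs = length(va), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Scaled-down phantom study configuration
#'
#' The study conditions used by [phantom_benchmark]: a 39/8/12
#' patient-level split mirroring the clinical cohort, 128-pixel slices at
#' a preserved 384 mm field of view, 12 slices per patient, and small
#' network configurations sized for CPU training. These are fixed choices,
#' not tuning knobs; the methods vignette discusses them.
#'
#' @param seed Master seed; all patient, initialization and shuffling seeds
#'   derive from it.
#' @return A list of configuration objects.
#' @export
benchmark_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    phantom = phantom_config(image_size = 128L, n_slices = 12L,
                             carina_slice = 4L, seed = seed),
    split = c(train = 39L, val = 8L, test = 12L),
    crop = crop_spec(),
    stage1 = train_config(
      network_config("dense_unet", n_classes = 6L, stem_width = 8L,
                     n_stages = 3L, block_layers = 2L, growth_rate = 6L,
                     seed = seed + 11L),
      epochs = 1L, lr = 2e-3, seed = seed + 12L,
      slices_per_patient = 3L, val_slices_per_patient = 2L),
    stage1_7c = train_config(
      network_config("dense_unet", n_classes = 7L, stem_width = 8L,
                     n_stages = 3L, block_layers = 2L, growth_rate = 6L,
                     seed = seed + 21L),
      epochs = 1L, lr = 2e-3, seed = seed + 22L,
      slices_per_patient = 3L, val_slices_per_patient = 2L),
    stage2 = train_config(
      network_config("residual_attention", n_classes = 1L,
                     widths = c(8L, 16L), seed = seed + 31L),
      epochs = 3L, lr = 2e-3, seed = seed + 32L),
    unet = train_config(
      network_config("unet", n_classes = 7L, widths = c(8L, 16L, 32L),
                     seed = seed + 41L),
      epochs = 1L, lr = 2e-3, seed = seed + 42L,
      slices_per_patient = 3L, val_slices_per_patient = 2L),
    crop_slices_per_patient = 6L,
    crop_seed = seed + 33L
  )
}

#' Run the two-step vs one-step vs U-Net phantom benchmark
#'
#' Generates a seeded phantom cohort, trains (a) the 6-class stage-1 dense
#' U-net plus the stage-2 residual attention crop network, (b) a 7-class
#' one-step dense U-net that includes the esophagus, and (c) a 7-class
#' baseline U-Net, then evaluates all three on the held-out test patients.
#'
#' @param seed Master seed.
#' @param cfg Configuration from [benchmark_config]; defaults to
#'   `benchmark_config(seed)`.
#' @param verbose Print stage progress.
#' @return List with the three `cohort_report`s (`two_step`, `one_step`,
#'   `unet`), their esophagus DSC means, and the fitted models.
#' @export
phantom_benchmark <- function(seed = 1L, cfg = benchmark_config(seed),
                              verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating phantom cohort (seed %d)", seed)
  cohort <- generate_cohort(cfg$phantom, sum(cfg$split), seed = cfg$phantom$seed)
  data <- split_cohort(cohort, cfg$split)
  gts <- lapply(data$test, function(s) s$labels)

  say("training stage 1 (6-class dense U-net)")
  s1 <- train_stage1(data, cfg$stage1)
  say("building stage-2 crops and training the residual attention net")
  crops_tr <- build_stage2_dataset(data$train, cfg$crop, jitter = TRUE,
                                   seed = cfg$crop_seed,
                                   slices_per_patient = cfg$crop_slices_per_patient)
  crops_val <- build_stage2_dataset(data$val, cfg$crop, jitter = FALSE,
                                    seed = cfg$crop_seed + 1L,
                                    slices_per_patient = cfg$crop_slices_per_patient)
  s2 <- train_stage2(crops_tr, cfg$stage2, crops_val)
  say("two-step inference on the test split")
  pred_two <- lapply(data$test, function(s) infer_two_step(s$ct, s1, s2, cfg$crop))

  say("training the one-step 7-class dense U-net")
  organs7 <- c(stage1_organs(), "esophagus")
  s7 <- train_stage1(data, cfg$stage1_7c, organs = organs7)
  pred_one <- lapply(data$test, function(s) predict_stage1(s7, s$ct))

  say("training the baseline U-Net")
  su <- train_stage1(data, cfg$unet, organs = organs7)
  pred_unet <- lapply(data$test, function(s) predict_stage1(su, s$ct))

  organs <- names(default_label_table())
  rep_two <- evaluate_cohort(pred_two, gts, organs)
  rep_one <- evaluate_cohort(pred_one, gts, organs)
  rep_unet <- evaluate_cohort(pred_unet, gts, organs)
  eso <- function(r) r$summary$mean[r$summary$organ == "esophagus" &
                                    r$summary$metric == "dsc"]
  list(two_step = rep_two, one_step = rep_one, unet = rep_unet,
       eso_dsc = c(two_step = eso(rep_two), one_step = eso(rep_one),
                   unet = eso(rep_unet)),
       models = list(stage1 = s1, stage2 = s2, one_step = s7, unet = su))
}
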