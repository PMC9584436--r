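# Memoized fixtures shared across test files. Everything is generated in
# code at test time; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# A small 3-volume dataset with a green channel, for unit tests.
tiny_ds <- function() memo("tiny_ds", function() {
  generate_dataset(3, layout_spec(seed = 0), green = TRUE)
})

# Ground-truth features for every volume of a dataset (worm frame from the
# volume itself, density context from ground-truth regions).
gt_features <- function(ds, preprocs = NULL) {
  lapply(seq_along(ds$volumes), function(vi) {
    v <- ds$volumes[[vi]]
    pp <- if (!is.null(preprocs)) preprocs[[vi]] else preprocess_volume(v$red)
    obj <- dplyr::rename(v$gt$objects, object_id = id)
    f <- featurize_volume(obj, pp$frame, depth = dim(v$red)[3],
                          source_mode = "regions",
                          regions = dplyr::rename(v$gt$regions,
                                                  object_id = id))
    f$label <- obj$object_id
    f$volume <- v$volume_index
    f
  })
}

# The full synthetic study used by the end-to-end checks: 40 easy-preset
# volumes of one animal, detector and recognizer trained on the first 30,
# volumes 31-40 held out.
study <- function() memo("study", function() {
  ds <- generate_dataset(40, synth_preset("easy", seed = 0))
  preprocs <- lapply(ds$volumes, function(v) preprocess_volume(v$red))
  ann <- dplyr::bind_rows(lapply(ds$volumes, function(v)
    dplyr::mutate(v$gt$regions, volume = v$volume_index)))
  detector <- train_detector(lapply(ds$volumes[1:30], function(v) v$red),
                             dplyr::filter(ann, volume <= 30),
                             seed = 1, preprocs = preprocs[1:30])
  feats <- gt_features(ds, preprocs)
  recognizer <- train_recognizer(dplyr::bind_rows(feats[1:30]), seed = 1)
  list(ds = ds, preprocs = preprocs, ann = ann, detector = detector,
       feats = feats, recognizer = recognizer, train_idx = 1:30,
       test_idx = 31:40)
})

# Held-out end-to-end results of the study: per-volume detection metrics and
# tracking accuracy through the full detect -> merge -> featurize -> assign
# chain.
study_eval <- function() memo("study_eval", function() {
  st <- study()
  rows <- lapply(st$test_idx, function(vi) {
    v <- st$ds$volumes[[vi]]
    pp <- st$preprocs[[vi]]
    pred <- detect_volume(v$red, st$detector, preproc = pp)
    det <- evaluate_detection(pred, v$gt$regions)
    mg <- merge_regions(pred)
    mrg <- evaluate_merging(mg$regions, v$gt$regions)
    f <- featurize_volume(mg$objects, pp$frame, depth = dim(v$red)[3],
                          source_mode = "regions", regions = mg$regions)
    a <- assign_ids_within(st$recognizer, f)
    lab <- label_objects(mg$objects, v$gt$objects)
    joined <- dplyr::left_join(a, dplyr::select(lab, object_id, true_id),
                               by = "object_id")
    tibble::tibble(volume = vi, tp = det$tp, n_pred = det$n_pred,
                   n_gt = det$n_gt, det_f1 = det$f1, merge_f1 = mrg$f1,
                   top1 = evaluate_tracking(joined))
  })
  dplyr::bind_rows(rows)
})
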