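square_mask <- function(specs, dim = c(20, 20)) {
  m <- matrix(0L, dim[1], dim[2])
  for (s in specs) m[s$rows, s$cols] <- s$id
  label_mask(m)
}

test_that("pairwise IoU matches pixel-counting on constructed squares", {
  pred <- square_mask(list(list(id = 1L, rows = 3:6, cols = 3:6)))
  truth <- square_mask(list(list(id = 1L, rows = 3:6, cols = 5:8)))
  iou <- pairwise_iou(pred, truth)
  expect_identical(nrow(iou$pairs), 1L)
  expect_equal(iou$pairs$iou, 8 / 24)  # 4x2 overlap, union 16+16-8

  ident <- pairwise_iou(truth, truth)
  expect_true(all(ident$pairs$iou == 1))

  disjoint <- pairwise_iou(
    square_mask(list(list(id = 1L, rows = 1:3, cols = 1:3))),
    square_mask(list(list(id = 1L, rows = 10:12, cols = 10:12))))
  expect_identical(nrow(disjoint$pairs), 0L)

  expect_error(pairwise_iou(pred, label_mask(matrix(0L, 5, 5))), "mismatch")
})

test_that("greedy matching resolves the contested two-pair case", {
  # one predicted object overlapping two truth objects at IoU 0.6 and 0.55
  iou <- structure(list(
    pairs = data.frame(pred = c(1L, 1L), truth = c(1L, 2L),
                       iou = c(0.6, 0.55)),
    pred_ids = 1L, truth_ids = c(1L, 2L)), class = "iou_table")
  m <- match_objects(iou)
  expect_identical(m$pairs$truth, 1L)
  expect_identical(c(m$tp, m$fp, m$fn), c(1L, 0L, 1L))
})

test_that("degenerate matchings produce the documented counts", {
  truth <- square_mask(lapply(1:5, function(i) {
    list(id = i, rows = (4 * i - 3):(4 * i - 1), cols = 2:4)
  }), dim = c(22, 8))
  perfect <- match_objects(pairwise_iou(truth, truth))
  expect_identical(c(perfect$tp, perfect$fp, perfect$fn), c(5L, 0L, 0L))

  empty <- match_objects(pairwise_iou(label_mask(matrix(0L, 22, 8)), truth))
  expect_identical(c(empty$tp, empty$fp, empty$fn), c(0L, 0L, 5L))
})

test_that("greedy matching equals exhaustive assignment on small scenes", {
  set.seed(5)
  for (rep in 1:30) {
    n_t <- sample(1:6, 1)
    truth_specs <- lapply(seq_len(n_t), function(i) {
      r0 <- 8 * ((i - 1) %% 3) + 2
      c0 <- 8 * ((i - 1) %/% 3) + 2
      list(id = i, rows = r0:(r0 + 4), cols = c0:(c0 + 4))
    })
    # jittered copies of the truth squares (one-to-one overlaps)
    pred_specs <- lapply(truth_specs, function(s) {
      dr <- sample(-1:1, 1); dc <- sample(-1:1, 1)
      list(id = s$id, rows = pmin(pmax(s$rows + dr, 1), 24),
           cols = pmin(pmax(s$cols + dc, 1), 24))
    })
    iou <- pairwise_iou(square_mask(pred_specs, c(24, 24)),
                        square_mask(truth_specs, c(24, 24)))
    greedy <- match_objects(iou, 0.5, method = "greedy")
    optimal <- match_objects(iou, 0.5, method = "optimal")
    oracle <- oracle_best_matching(iou$pairs[iou$pairs$iou >= 0.5, ,
                                             drop = FALSE])
    expect_identical(greedy$tp, optimal$tp)
    expect_identical(optimal$tp, as.integer(oracle$card))
    expect_equal(sum(optimal$pairs$iou), oracle$total, tolerance = 1e-12)
  }
})

test_that("detection scores follow the formula oracle", {
  m <- structure(list(pairs = data.frame(), tp = 8L, fp = 2L, fn = 2L,
                      iou_threshold = 0.5), class = "match_result")
  sc <- detection_scores(m)
  expect_equal(sc$precision, 0.8)
  expect_equal(sc$recall, 0.8)
  expect_equal(sc$f1, 0.8)
  expect_equal(sc$accuracy, 8 / 12)

  perfect <- structure(list(pairs = data.frame(), tp = 4L, fp = 0L, fn = 0L,
                            iou_threshold = 0.5), class = "match_result")
  expect_true(all(detection_scores(perfect)[, c("precision", "recall",
                                                "accuracy", "f1")] == 1))

  degenerate <- structure(list(pairs = data.frame(), tp = 0L, fp = 3L,
                               fn = 2L, iou_threshold = 0.5),
                          class = "match_result")
  sd_ <- detection_scores(degenerate)
  expect_identical(c(sd_$precision, sd_$recall), c(0, 0))
  expect_true(is.na(sd_$f1))

  nothing <- structure(list(pairs = data.frame(), tp = 0L, fp = 0L, fn = 0L,
                            iou_threshold = 0.5), class = "match_result")
  expect_error(detection_scores(nothing), "undefined")
})

test_that("scores are symmetric under pred/truth swap and relabeling", {
  s <- generate_scene(scene_params(n_cells = 40, seed = 6))
  pred <- segment_nuclei(s$channels$nuclear)
  truth <- label_mask(s$truth_nuclei_mask)
  fwd <- evaluate_detection(pred, truth)
  rev_ <- evaluate_detection(truth, pred)
  expect_identical(fwd$tp, rev_$tp)
  expect_identical(fwd$fp, rev_$fn)
  expect_identical(fwd$precision, rev_$recall)
  # relabeled prediction scores identically
  relabeled <- pred$labels
  relabeled[relabeled > 0L] <- relabeled[relabeled > 0L] + 1000L
  expect_identical(evaluate_detection(label_mask(relabeled), truth), fwd)
})
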