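make_table <- function(rows, host) {
  m <- do.call(rbind, rows)
  psm_table(m, host)
}

test_that("host-specific calling applies presence, absence and spectra floor", {
  a <- make_table(list(X = c(4L, 3L, 4L), Y = c(5L, 5L, 0L),
                       Z = c(3L, 3L, 3L), HupL = c(20L, 15L, 9L),
                       W = c(2L, 2L, 2L)), "pea")
  b <- make_table(list(X = c(0L, 0L, 0L), W = c(0L, 1L, 0L)), "lentil")
  calls <- call_host_specific(a, b, min_accumulated = 10)
  # X passes all three criteria (accumulated 11 >= 10, absent in lentil)
  expect_setequal(calls$a$id, c("X", "HupL"))
  expect_equal(calls$a$accumulated_psm[calls$a$id == "X"], 11L)
  # Y misses one replicate; Z accumulates only 9; W has one lentil spectrum
  expect_false(any(c("Y", "Z", "W") %in% calls$a$id))
  expect_equal(nrow(calls$b), 0L)
})

test_that("absence includes proteins not listed in the other host's table", {
  a <- make_table(list(P = c(6L, 6L, 6L)), "pea")
  b <- make_table(list(Q = c(1L, 1L, 1L)), "lentil")
  calls <- call_host_specific(a, b)
  expect_equal(calls$a$id, "P")
})

test_that("host-specific calls are disjoint and match the brute-force oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    ids <- sprintf("P%03d", seq_len(n))
    mk <- function() {
      m <- matrix(rbinom(3 * n, size = 1, prob = 0.6) *
                    rpois(3 * n, lambda = 4), ncol = 3,
                  dimnames = list(ids, paste0("rep", 1:3)))
      storage.mode(m) <- "integer"
      m
    }
    ca <- mk(); cb <- mk()
    calls <- call_host_specific(psm_table(ca, "A"), psm_table(cb, "B"))
    oracle <- brute_host_specific(ca, cb)
    expect_setequal(calls$a$id, oracle$a)
    expect_setequal(calls$b$id, oracle$b)
    expect_length(intersect(calls$a$id, calls$b$id), 0L)
  }
})

test_that("raising the spectra floor never adds a call", {
  set.seed(5)
  ids <- sprintf("P%02d", 1:50)
  ca <- matrix(rpois(150, 4), ncol = 3, dimnames = list(ids, NULL))
  cb <- matrix(rpois(150, 4) * rbinom(150, 1, 0.3), ncol = 3,
               dimnames = list(ids, NULL))
  storage.mode(ca) <- "integer"; storage.mode(cb) <- "integer"
  ta <- psm_table(ca, "A"); tb <- psm_table(cb, "B")
  prev <- NULL
  for (floor_val in c(0, 5, 10, 15, 20)) {
    cur <- call_host_specific(ta, tb, floor_val)
    cur_ids <- c(cur$a$id, cur$b$id)
    if (!is.null(prev)) expect_true(all(cur_ids %in% prev))
    prev <- cur_ids
  }
})

test_that("iTRAQ classification has inclusive, symmetric boundaries", {
  expect_equal(classify_itraq(2.62), "pea_over")
  expect_equal(classify_itraq(2.00), "pea_over")
  expect_equal(classify_itraq(0.50), "lentil_over")
  expect_equal(classify_itraq(0.17), "lentil_over")
  expect_equal(classify_itraq(1.0), "not_significant")
  expect_equal(classify_itraq(1.99), "not_significant")
  expect_error(classify_itraq(2.5, threshold = 1), "> 1")
  expect_error(classify_itraq(-2), "positive")
  # raising the threshold never adds a significant label
  set.seed(2)
  ratios <- exp(rnorm(200, 0, 0.6))
  prev <- NULL
  for (th in c(1.5, 2, 3, 5)) {
    sig <- which(classify_itraq(ratios, th) != "not_significant")
    if (!is.null(prev)) expect_true(all(sig %in% prev))
    prev <- sig
  }
})

test_that("reconciliation merges presence calls with iTRAQ labels", {
  a <- make_table(list(X = c(4L, 4L, 4L), V = c(6L, 6L, 6L)), "pea")
  b <- make_table(list(M = c(5L, 5L, 5L)), "lentil")
  calls <- call_host_specific(a, b)
  itraq <- data.frame(id = c("V", "M", "N"), ratio = c(2.5, 0.4, 1.1),
                      stringsAsFactors = FALSE)
  rec <- reconcile_calls(calls, itraq)
  # pea-specific, no ratio measurable: agreement by silence
  expect_equal(rec$itraq_label[rec$id == "X"], "not_measurable")
  expect_true(rec$agreement[rec$id == "X"])
  # pea-specific and pea_over: both methods point at pea
  expect_equal(rec$itraq_label[rec$id == "V"], "pea_over")
  expect_true(rec$agreement[rec$id == "V"])
  # lentil-specific but pea-shifted ratio would conflict
  itraq2 <- data.frame(id = "M", ratio = 3.0, stringsAsFactors = FALSE)
  rec2 <- reconcile_calls(calls, itraq2)
  expect_false(rec2$agreement[rec2$id == "M"])
})
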