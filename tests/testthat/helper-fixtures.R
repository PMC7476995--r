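# Shared fixtures and scoring helpers for the test suite.

# Greedy one-to-one matching of ground-truth centroids to detection boxes;
# returns counts needed for precision/recall/F1.
match_detections <- function(field, boxes) {
  used <- rep(FALSE, nrow(boxes))
  tp <- 0L
  unmatched <- character(0)
  for (cell in field$cells) {
    hit <- which(!used &
                   boxes$row0 <= cell$centroid["row"] &
                   boxes$row1 >= cell$centroid["row"] &
                   boxes$col0 <= cell$centroid["col"] &
                   boxes$col1 >= cell$centroid["col"])
    if (length(hit) > 0) {
      tp <- tp + 1L
      used[hit[1]] <- TRUE
    } else {
      unmatched <- c(unmatched, cell$cell_class)
    }
  }
  list(tp = tp, n_truth = length(field$cells), n_pred = nrow(boxes),
       f1 = if (nrow(boxes) + length(field$cells) == 0) 1 else
         2 * tp / (nrow(boxes) + length(field$cells)),
       unmatched = unmatched)
}

nucleus_iou <- function(mask, truth_nucleus) {
  inter <- sum(mask == 3L & truth_nucleus)
  uni <- sum(mask == 3L | truth_nucleus)
  if (uni == 0) return(1)
  inter / uni
}

# mask built from ground truth, in segment_cell() label coding
truth_to_mask <- function(cell_mask, nucleus_mask) {
  m <- matrix(0L, nrow(cell_mask), ncol(cell_mask))
  m[cell_mask] <- 2L
  m[nucleus_mask] <- 3L
  m
}

# well-separated two-class Gaussian feature records for classifier tests
separable_records <- function(n_per_class, seed = 1) {
  stopifnot(n_per_class >= 5)
  marrowdiff:::with_local_seed(seed, {
    mk <- function(label, shift) {
      x <- as.data.frame(matrix(stats::rnorm(n_per_class *
                                               length(feature_names()),
                                             mean = shift, sd = 0.5),
                                nrow = n_per_class))
      names(x) <- feature_names()
      x$label <- label
      x
    }
    rbind(mk("myeloblast", 0), mk("neutrophil", 10))
  })
}

# brute-force Passing-Bablok slope/intercept oracle (independent of the
# package implementation): exhaustive pairwise slopes with the K shift
pb_oracle <- function(x, y) {
  n <- length(x)
  s <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- c(s, if (dx == 0) sign(dy) * Inf else dy / dx)
    }
  }
  s <- s[s != -1]
  s <- sort(s)
  N <- length(s)
  K <- sum(s < -1)
  b <- if (N %% 2 == 1) s[(N + 1) / 2 + K] else
    mean(c(s[N / 2 + K], s[N / 2 + 1 + K]))
  list(slope = b, intercept = stats::median(y - b * x))
}
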