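# Shared fixtures and independent brute-force oracles.

# disk of given diameter stamped into a label matrix
stamp_disk <- function(mask, center, diameter, label) {
  rr <- row(mask) - center[1]
  cc <- col(mask) - center[2]
  mask[rr^2 + cc^2 <= (diameter / 2)^2] <- label
  mask
}

disk_mask <- function(H, W, centers, diameter, labels = seq_len(nrow(centers))) {
  m <- matrix(0L, H, W)
  for (i in seq_len(nrow(centers))) m <- stamp_disk(m, centers[i, ], diameter, labels[i])
  m
}

# brightfield-like rendering of a label mask: flat background, dark rim at
# any pixel whose 4-neighbour carries a different label
rimmed_image <- function(lab, background = 100, rim_depth = 40, noise_sd = 0) {
  H <- nrow(lab); W <- ncol(lab)
  rimmed <- matrix(FALSE, H, W)
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    shifted <- matrix(NA_integer_, H, W)
    rs <- max(1, 1 + s[1]):min(H, H + s[1])
    cs <- max(1, 1 + s[2]):min(W, W + s[2])
    shifted[rs, cs] <- lab[rs - s[1], cs - s[2]]
    rimmed <- rimmed | (!is.na(shifted) & shifted != lab)
  }
  img <- matrix(background, H, W)
  img[rimmed & lab > 0] <- background - rim_depth
  if (noise_sd > 0) img <- img + rnorm(H * W, 0, noise_sd)
  img
}

# random label mask of blobby rectangles (possibly overlapping -> later wins)
random_label_mask <- function(H, W, n_labels, max_extent = 12) {
  m <- matrix(0L, H, W)
  for (lb in seq_len(n_labels)) {
    h <- sample.int(max_extent, 1); w <- sample.int(max_extent, 1)
    r <- sample.int(H - h + 1, 1); c <- sample.int(W - w + 1, 1)
    m[r:(r + h - 1), c:(c + w - 1)] <- lb
  }
  m
}

# brute-force all-label-pairs pixel-set-intersection oracle for the overlap
# matching criterion; returns the same structure as match_segments()
oracle_match_overlap <- function(candidate, reference) {
  cls <- sort(unique(candidate[candidate > 0]))
  rls <- sort(unique(reference[reference > 0]))
  ref_hits <- integer(length(rls))
  cand_hits <- integer(length(cls))
  for (i in seq_along(rls)) {
    rpix <- which(reference == rls[i])
    for (j in seq_along(cls)) {
      cpix <- which(candidate == cls[j])
      if (length(intersect(rpix, cpix)) > 0) {
        ref_hits[i] <- ref_hits[i] + 1L
        cand_hits[j] <- cand_hits[j] + 1L
      }
    }
  }
  list(reference_hits = tibble::tibble(label = as.integer(rls), n_hits = ref_hits),
       candidate_hits = tibble::tibble(label = as.integer(cls), n_hits = cand_hits))
}

oracle_quality_metrics <- function(candidate, reference) {
  h <- oracle_match_overlap(candidate, reference)
  n_ref <- nrow(h$reference_hits); n_cand <- nrow(h$candidate_hits)
  tibble::tibble(
    n_candidate = n_cand, n_reference = n_ref,
    segments_per_nucleus = n_cand / n_ref,
    fn_ratio = sum(h$reference_hits$n_hits == 0) / n_ref,
    fp_ratio = if (n_cand == 0) 0 else sum(h$candidate_hits$n_hits == 0) / n_cand)
}

# brute-force membership check for the Gaussian size band
oracle_size_band <- function(areas, min_area, n_sd) {
  kept <- areas[areas >= min_area]
  mu <- mean(kept); sigma <- stats::sd(kept)
  vapply(areas, function(a)
    a >= min_area && a >= mu - n_sd * sigma && a <= mu + n_sd * sigma, logical(1))
}
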