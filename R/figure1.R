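#' Worked-example phantom pair with known anatomical and functional V20
#'
#' Builds two fully deterministic phantom bundles emulating the published
#' side-by-side DVH comparison of a patient who developed grade >= 2 lung
#' toxicity and one who did not: both have anatomical V20 = 25%, while
#' the functional V20 values differ (RILT case: Q-V20 = 35%, V-V20 = 33%;
#' non-RILT case: Q-V20 = 20%, V-V20 = 22%).
#'
#' The construction is combinatorial, not a tuned realistic phantom: the
#' lung is a box of exactly 10,000 voxels; the first 2,500 voxels (in
#' array order) receive 30 Gy and the rest 10 Gy, fixing V20 at 25%; the
#' perfusion-functional region is 2,000 voxels of which exactly
#' 700 (RILT) / 400 (non-RILT) lie in the high-dose block, and the
#' ventilation-functional region is 3,000 voxels of which 990 / 660 do,
#' so the functional V20 fractions are exact by allocation. Activity is
#' two-level -- 1.0 inside the intended functional region, 0.1 in the
#' rest of the lung -- so 30%-of-maximum segmentation recovers the
#' intended regions voxel-for-voxel. An internal brute-force voxel count
#' re-verifies all six percentages before the fixture is returned.
#'
#' @return `list(rilt_case = , non_rilt_case = )`, each a bundle
#'   `list(dose, q_activity, v_activity, lung)`.
#' @examples
#' fx <- figure1_fixture()
#' q <- segment_functional(fx$rilt_case$q_activity, fx$rilt_case$lung,
#'                         0.30, "perfusion")
#' vx(fx$rilt_case$dose, q)  # 35
#' @export
figure1_fixture <- function() {
  shape <- c(24L, 29L, 24L)
  spacing <- c(2.5, 2.5, 2.5)
  # lung: 20 x 25 x 20 box, 10,000 voxels, inset by 2 voxels
  lung_v <- array(FALSE, dim = shape)
  lung_v[3:22, 3:27, 3:22] <- TRUE
  n_lung <- sum(lung_v)
  lung_idx <- which(lung_v)  # array order: deterministic linearization

  build_case <- function(q_overlap, v_overlap) {
    n_high <- 2500L
    n_q <- 2000L
    n_v <- 3000L
    dose_v <- array(0, dim = shape)
    dose_v[lung_idx] <- 10
    dose_v[lung_idx[seq_len(n_high)]] <- 30

    two_level <- function(member) {
      a <- array(0, dim = shape)
      a[lung_idx] <- 0.1
      a[member] <- 1.0
      a
    }
    q_members <- c(lung_idx[seq_len(q_overlap)],
                   lung_idx[(n_high + 1):(n_high + n_q - q_overlap)])
    v_members <- c(lung_idx[seq_len(v_overlap)],
                   lung_idx[(n_high + 1):(n_high + n_v - v_overlap)])

    list(dose = image_grid(dose_v, spacing),
         q_activity = image_grid(two_level(q_members), spacing),
         v_activity = image_grid(two_level(v_members), spacing),
         lung = binary_mask(lung_v, spacing))
  }

  fixture <- list(
    rilt_case = build_case(q_overlap = 700L, v_overlap = 990L),
    non_rilt_case = build_case(q_overlap = 400L, v_overlap = 660L)
  )

  # consistency check: recompute all six percentages by brute-force count
  expected <- list(rilt_case = c(25, 35, 33), non_rilt_case = c(25, 20, 22))
  for (case in names(fixture)) {
    b <- fixture[[case]]
    hi <- b$dose$values >= 20 & b$lung$values
    got <- c(100 * sum(hi) / n_lung,
             vapply(list(b$q_activity, b$v_activity), function(act) {
               fn <- act$values >= 0.3 * max(act$values[b$lung$values]) & b$lung$values
               100 * sum(hi & fn) / sum(fn)
             }, numeric(1)))
    if (!isTRUE(all.equal(got, expected[[case]]))) {
      abort(paste0("internal fixture consistency check failed for ", case, "."))
    }
  }
  fixture
}
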