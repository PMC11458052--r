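#' Build the same/different pair pool
#'
#' Composes the pair pool for one participant: 30 *same* pairs (two different
#' images of the same identity, so the task taps identity recognition rather
#' than image matching) and 30 *different* pairs (images of two different
#' identities), replicated across every condition. With the default 10
#' identities x 3 images, the same-pairs are all within-identity image pairs
#' (10 x 3 = 30) and the different-pairs are built from a random cyclic
#' arrangement of the 30 images with no same-identity neighbours, so that —
#' as in the experiment — every image is used exactly twice in same pairs and
#' twice in different pairs.
#'
#' @param n_identities number of identities (>= 2).
#' @param images_per_identity images per identity (>= 2).
#' @param seed integer seed.
#' @return data frame with columns `pair_id`, `is_same`, `probe_image_id`,
#'   `target_image_id` (image ids are `"id<i>_img<k>"`).
#' @export
build_pairs <- function(n_identities = 10, images_per_identity = 3, seed = 1) {
  if (n_identities < 2L)
    stop("need at least 2 identities to form different-identity pairs",
         call. = FALSE)
  if (images_per_identity < 2L)
    stop("need at least 2 images per identity to form same pairs",
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  img_id <- function(i, k) sprintf("id%d_img%d", i, k)
  identity_of <- rep(seq_len(n_identities), each = images_per_identity)
  images <- as.vector(t(outer(seq_len(n_identities),
                              seq_len(images_per_identity), img_id)))

  # same pairs: all unordered within-identity image pairs
  same <- do.call(rbind, lapply(seq_len(n_identities), function(i) {
    cmb <- utils::combn(seq_len(images_per_identity), 2)
    data.frame(probe = img_id(i, cmb[1, ]), target = img_id(i, cmb[2, ]))
  }))
  n_same <- nrow(same)  # 30 for the default 10 x 3 set

  # different pairs: random cycle over all images, adjacent identities distinct;
  # each image appears exactly twice (once as probe, once as target)
  for (attempt in seq_len(1000)) {
    ord <- sample(length(images))
    ids <- identity_of[ord]
    if (all(ids != c(ids[-1L], ids[1L]))) break
    if (attempt == 1000)
      stop("could not arrange different-identity pairs; too few identities",
           call. = FALSE)
  }
  diff <- data.frame(probe = images[ord],
                     target = images[c(ord[-1L], ord[1L])])

  # randomize probe/target roles within each pair
  flip <- function(df) {
    sw <- sample(c(TRUE, FALSE), nrow(df), replace = TRUE)
    tmp <- df$probe[sw]; df$probe[sw] <- df$target[sw]; df$target[sw] <- tmp
    df
  }
  same <- flip(same); diff <- flip(diff)

  out <- rbind(
    data.frame(pair_id = sprintf("same%02d", seq_len(n_same)), is_same = TRUE,
               probe_image_id = same$probe, target_image_id = same$target),
    data.frame(pair_id = sprintf("diff%02d", seq_len(nrow(diff))),
               is_same = FALSE,
               probe_image_id = diff$probe, target_image_id = diff$target))
  rownames(out) <- NULL
  out
}

#' Build a blocked trial schedule
#'
#' Lays out the main experiment for one subject: 90 blocks of 14 trials
#' (1260 trials). Stimulus type (natural / inverted / negated) is blocked;
#' blocks come in consecutive triplets containing each stimulus type once in
#' random order (30 blocks per type). Each block holds two trials of each of
#' the six orientation filters plus two full-spectrum trials, giving 60
#' trials — the full pair pool, 50\% same — per stimulus type x filter
#' condition. Pairs are dealt to blocks uniformly at random without
#' replacement within each condition, and trial order is shuffled within
#' blocks.
#'
#' @param pairs pair pool from [build_pairs()].
#' @param seed integer seed.
#' @param subject_id optional subject label attached to every row.
#' @param filter_labels orientation filter labels; full spectrum is always
#'   appended.
#' @return data frame of trials: `subject`, `block_index`, `trial_index`
#'   (within block), `stimulus_type`, `filter`, `pair_id`, `is_same`,
#'   `probe_image_id`, `target_image_id`.
#' @export
build_schedule <- function(pairs, seed = 1, subject_id = "s01",
                           filter_labels = as.character(seq(0, 150, by = 30))) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "is_same") %in% names(pairs)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  types <- c("natural", "inverted", "negated")
  n_triplets <- 30L
  conds <- c(filter_labels, "fullspectrum")
  trials_per_cond_block <- 2L
  blocks_per_type <- n_triplets

  # assign stimulus types to blocks, triplet by triplet
  block_type <- unlist(lapply(seq_len(n_triplets), function(i) sample(types)))

  # for each type x condition, deal the pair pool 2-per-block over its blocks
  sched <- vector("list", 3L * length(conds))
  idx <- 1L
  for (ty in types) {
    ty_blocks <- which(block_type == ty)
    for (cond in conds) {
      dealt <- pairs[sample(nrow(pairs)), ]
      if (nrow(dealt) != trials_per_cond_block * blocks_per_type)
        stop("pair pool size must equal trials per condition (60)",
             call. = FALSE)
      dealt$block_index <- rep(ty_blocks, each = trials_per_cond_block)
      dealt$stimulus_type <- ty
      dealt$filter <- cond
      sched[[idx]] <- dealt
      idx <- idx + 1L
    }
  }
  sched <- do.call(rbind, sched)

  # shuffle trial order within each block
  sched <- sched[order(sched$block_index, sample(nrow(sched))), ]
  sched$trial_index <- stats::ave(seq_len(nrow(sched)), sched$block_index,
                                  FUN = seq_along)
  sched$subject <- subject_id
  rownames(sched) <- NULL
  sched[, c("subject", "block_index", "trial_index", "stimulus_type",
            "filter", "pair_id", "is_same", "probe_image_id",
            "target_image_id")]
}
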