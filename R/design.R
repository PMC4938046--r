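#' Chance level of landing on a cued flower
#'
#' Under uniformly random flower choice the probability of landing on a
#' flower carrying an added cue is simply the fraction of cued flowers in
#' the array: 4 of 12 by default, i.e. 1/3 (33.3%).
#'
#' @param n_cued Number of flowers carrying the added cue.
#' @param n_flowers Total number of flowers in the array.
#' @return The chance landing probability `n_cued / n_flowers`.
#' @examples
#' chance_level()        # 1/3
#' @export
chance_level <- function(n_cued = 4L, n_flowers = 12L) {
  stopifnot(n_cued >= 0, n_flowers >= 1, n_cued <= n_flowers)
  n_cued / n_flowers
}

#' Relative reward likelihood of cued versus randomly chosen flowers
#'
#' In the cue-training array, rewards sit only on a subset of the cued
#' flowers (2 of the 4 cued flowers by default, out of 12 flowers total, so
#' cues predict reward imperfectly — mimicking depletion by competitors).
#' A forager landing on a cued flower finds a reward with probability
#' `n_rewarded_cued / n_cued`, while a forager landing uniformly at random
#' finds one with probability `n_rewarded / n_flowers`. The ratio of the
#' two — 3 under the defaults, (2/4)/(2/12) — is how much more likely a
#' cue-following forager is to be rewarded.
#'
#' @param n_rewarded_cued Rewarded flowers among the cued ones.
#' @param n_cued Cued flowers in the array.
#' @param n_rewarded Rewarded flowers in the whole array.
#' @param n_flowers Flowers in the whole array.
#' @return The relative reward likelihood (a ratio >= 0).
#' @examples
#' cue_reward_advantage()    # 3
#' @export
cue_reward_advantage <- function(n_rewarded_cued = 2L, n_cued = 4L,
                                 n_rewarded = 2L, n_flowers = 12L) {
  stopifnot(n_cued >= 1, n_flowers >= 1, n_rewarded_cued <= n_cued,
            n_rewarded >= 1, n_rewarded <= n_flowers)
  (n_rewarded_cued / n_cued) / (n_rewarded / n_flowers)
}
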