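#' Construct a sentence-quadruplet lexicon
#'
#' A quadruplet cross-pairs two agents with two actions and supplies the four
#' patients completing the resulting subject-verb-object sentences. Patient
#' `patients[i, j]` completes agent `i` + action `j` ("the bird eats the
#' worm" style). Within a quadruplet all four patients must be distinct, as
#' must the two agents and the two actions: the balanced condition design
#' relies on every word/image serving once in each role.
#'
#' @param quadruplets A list; each element is a list with `agents` (2
#'   labels), `actions` (2 labels) and `patients` (2x2 character matrix,
#'   rows = agents, columns = actions).
#' @return A `vwp_lexicon` object.
#' @export
lexicon <- function(quadruplets) {
  for (i in seq_along(quadruplets)) {
    q <- quadruplets[[i]]
    if (!all(c("agents", "actions", "patients") %in% names(q))) {
      stop("invalid lexicon: quadruplet ", i,
           " must have agents, actions and patients")
    }
    if (length(q$agents) != 2 || anyDuplicated(q$agents)) {
      stop("invalid lexicon: quadruplet ", i, " needs 2 distinct agents")
    }
    if (length(q$actions) != 2 || anyDuplicated(q$actions)) {
      stop("invalid lexicon: quadruplet ", i, " needs 2 distinct actions")
    }
    p <- q$patients
    if (!is.matrix(p) || !all(dim(p) == c(2, 2)) || anyDuplicated(c(p))) {
      stop("invalid lexicon: quadruplet ", i,
           " needs a 2x2 matrix of 4 distinct patients")
    }
  }
  structure(list(quadruplets = quadruplets), class = "vwp_lexicon")
}

#' Default six-quadruplet lexicon
#'
#' Six quadruplets (24 sentences) of concrete, child-familiar words, used by
#' the synthetic cohort generator.
#'
#' @return A `vwp_lexicon` object with 6 quadruplets.
#' @export
default_lexicon <- function() {
  quad <- function(agents, actions, patients) {
    list(agents = agents, actions = actions,
         patients = matrix(patients, 2, 2, byrow = TRUE))
  }
  lexicon(list(
    quad(c("bird", "worker"), c("eats", "builds"),
         c("worm", "nest", "rice", "building")),
    quad(c("cat", "girl"), c("catches", "draws"),
         c("mouse", "sun", "fish", "picture")),
    quad(c("rabbit", "boy"), c("nibbles", "kicks"),
         c("carrot", "box", "cake", "ball")),
    quad(c("monkey", "dad"), c("peels", "drives"),
         c("banana", "cart", "orange", "truck")),
    quad(c("dog", "mum"), c("chews", "washes"),
         c("bone", "sock", "bread", "cup")),
    quad(c("bee", "chef"), c("visits", "fries"),
         c("flower", "garden", "egg", "pan"))
  ))
}

# Condition labels in canonical order.
vwp_conditions <- function() {
  c("target", "agent_related", "action_related", "unrelated")
}

#' Build the balanced trial designs for a lexicon
#'
#' Expands each quadruplet into its four trials. For the sentence formed by
#' agent `i` and action `j`, the four displayed patients take the roles:
#' target `patients[i, j]`, agent-related `patients[i, 3 - j]` (same agent,
#' other action), action-related `patients[3 - i, j]`, unrelated
#' `patients[3 - i, 3 - j]`. This makes every word within a quadruplet serve
#' each condition exactly once, so each image is its own perceptual control.
#' Conditions are rotated over the four screen positions with a Latin
#' square, so each condition also appears once at each position within a
#' quadruplet.
#'
#' @param lex A [lexicon()] object.
#' @return A tibble with one row per trial: `trial_id`, `quadruplet_id`,
#'   `sentence_id` (1-4), the sentence words (`agent`, `action`, `patient`),
#'   the condition shown at each screen position (`cond_pos1`..`cond_pos4`),
#'   the word shown there (`word_pos1`..`word_pos4`), and the timing
#'   landmark columns from [timing_landmarks()].
#' @export
build_stimulus_set <- function(lex) {
  stopifnot(inherits(lex, "vwp_lexicon"))
  conds <- vwp_conditions()
  lm <- timing_landmarks()
  rows <- list()
  trial <- 0L
  for (qi in seq_along(lex$quadruplets)) {
    q <- lex$quadruplets[[qi]]
    sid <- 0L
    for (i in 1:2) for (j in 1:2) {
      sid <- sid + 1L
      trial <- trial + 1L
      word_of_cond <- c(
        target = q$patients[i, j],
        agent_related = q$patients[i, 3 - j],
        action_related = q$patients[3 - i, j],
        unrelated = q$patients[3 - i, 3 - j]
      )
      # Latin square: position p shows condition (sid + p) mod 4, so across
      # the quadruplet's four sentences each condition visits each position.
      cond_at_pos <- conds[((sid + 0:3) %% 4) + 1]
      rows[[trial]] <- tibble::tibble(
        trial_id = trial, quadruplet_id = qi, sentence_id = sid,
        agent = q$agents[i], action = q$actions[j],
        patient = q$patients[i, j],
        cond_pos1 = cond_at_pos[1], cond_pos2 = cond_at_pos[2],
        cond_pos3 = cond_at_pos[3], cond_pos4 = cond_at_pos[4],
        word_pos1 = unname(word_of_cond[cond_at_pos[1]]),
        word_pos2 = unname(word_of_cond[cond_at_pos[2]]),
        word_pos3 = unname(word_of_cond[cond_at_pos[3]]),
        word_pos4 = unname(word_of_cond[cond_at_pos[4]]),
        verb_onset = lm[["verb_onset"]],
        patient_onset = lm[["patient_onset"]],
        sentence_offset = lm[["sentence_offset"]],
        window_end = lm[["window_end"]]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      trial_id = integer(), quadruplet_id = integer(), sentence_id = integer(),
      agent = character(), action = character(), patient = character(),
      cond_pos1 = character(), cond_pos2 = character(),
      cond_pos3 = character(), cond_pos4 = character(),
      word_pos1 = character(), word_pos2 = character(),
      word_pos3 = character(), word_pos4 = character(),
      verb_onset = numeric(), patient_onset = numeric(),
      sentence_offset = numeric(), window_end = numeric()
    ))
  }
  dplyr::bind_rows(rows)
}

# Screen position of the target on each trial (1-4).
target_position <- function(designs) {
  cond_mat <- as.matrix(designs[paste0("cond_pos", 1:4)])
  apply(cond_mat, 1, function(r) which(r == "target"))
}

#' Check the pseudo-randomization constraints of a trial order
#'
#' The two presentation constraints: the target image may not occupy the
#' same screen position on more than two consecutive trials, and two trials
#' from the same quadruplet may not be adjacent.
#'
#' @param designs Ordered trial-design tibble from [build_stimulus_set()].
#' @return `TRUE` if both constraints hold, otherwise `FALSE`.
#' @export
check_trial_order <- function(designs) {
  n <- nrow(designs)
  if (n < 2) return(TRUE)
  tp <- target_position(designs)
  runs <- rle(tp)
  if (any(runs$lengths > 2)) return(FALSE)
  q <- designs$quadruplet_id
  all(q[-1] != q[-n])
}

#' Pseudo-randomize trial designs under the presentation constraints
#'
#' Draws random permutations until one satisfies [check_trial_order()]
#' (rejection sampling with a bounded number of restarts). A fixed seed
#' yields a fixed order.
#'
#' @param designs Trial designs from [build_stimulus_set()].
#' @param seed Integer seed.
#' @param max_restarts Attempts before giving up.
#' @return The reordered tibble, with an attribute `restarts` recording how
#'   many draws were rejected.
#' @export
pseudo_randomize <- function(designs, seed, max_restarts = 10000) {
  n <- nrow(designs)
  if (n < 2) return(designs)
  tp <- target_position(designs)
  q <- designs$quadruplet_id
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(max_restarts)) {
      ord <- sample.int(n)
      tpo <- tp[ord]
      if (any(rle(tpo)$lengths > 2)) next
      qo <- q[ord]
      if (any(qo[-1] == qo[-n])) next
      cand <- designs[ord, ]
      attr(cand, "restarts") <- attempt - 1L
      return(cand)
    }
    stop("pseudo_randomize: no constraint-satisfying order found after ",
         max_restarts, " restarts")
  })
}
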