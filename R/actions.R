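#' Enumerate the 18-action elbow movement grid
#'
#' The assessment protocol defines nine planar spatial targets — three
#' movement directions (45, 90, 135 degrees) crossed with three radial
#' distances (Near, Mid, Far) — each visited in two motion phases, reaching
#' out (elbow extension) and returning (elbow flexion). Action IDs follow a
#' direction-major, distance-minor numbering: IDs 1-6 are the 45-degree
#' targets, 7-12 the 90-degree targets, 13-18 the 135-degree targets; within
#' a direction targets run Near to Far, and for each target the odd ID is the
#' reach-out (extension, parity 0) and the following even ID the return
#' (flexion, parity 1).
#'
#' @return A data frame with one row per action and columns `action_id`
#'   (1-18), `direction_deg` (45/90/135), `distance` (factor Near/Mid/Far),
#'   and `parity` (0 = reach out / extension, 1 = return / flexion).
#' @examples
#' grid <- enumerate_actions()
#' nrow(grid)              # 18
#' grid[grid$action_id == 14, ]  # 135 degrees, Near, return
#' @export
enumerate_actions <- function() {
  action_id <- 1:18
  direction_deg <- c(45, 90, 135)[ceiling(action_id / 6)]
  within <- (action_id - 1) %% 6
  distance <- factor(c("Near", "Mid", "Far")[within %/% 2 + 1],
                     levels = c("Near", "Mid", "Far"))
  parity <- action_id %% 2 == 0
  data.frame(action_id = action_id,
             direction_deg = direction_deg,
             distance = distance,
             parity = as.integer(parity))
}

#' Action parity (motion phase) from an action ID
#'
#' Odd IDs are reach-out / extension trials (parity 0); even IDs are
#' return / flexion trials (parity 1).
#'
#' @param action_id Integer vector of action IDs in 1..18.
#' @return Integer vector of parities in \{0, 1\}.
#' @export
action_parity <- function(action_id) {
  check_action_id(action_id)
  as.integer(action_id %% 2 == 0)
}

check_action_id <- function(action_id) {
  if (!all(action_id %in% 1:18))
    stop("action_id must be an integer in 1..18", call. = FALSE)
  invisible(action_id)
}

#' The eight recorded forearm and upper-arm muscles
#'
#' Electrode sites in recording order: flexor carpi radialis (FCR), extensor
#' carpi radialis (ECR), flexor carpi ulnaris (FCU), brachioradialis (BR),
#' extensor carpi ulnaris (ECU), biceps brachii (BB), triceps brachii long
#' head (TBL) and triceps brachii lateral head (TBLa).
#'
#' @return Character vector of the 8 muscle abbreviations.
#' @export
muscle_names <- function() {
  c("FCR", "ECR", "FCU", "BR", "ECU", "BB", "TBL", "TBLa")
}
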