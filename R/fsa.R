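## Finite-state automaton for shared movement/speed control. States encode
## the current speed adjustment of the falling block group; inputs are the
## decoded imagery classes, the per-second command-count comparisons, and
## the game events.

#' FSA state and input alphabets
#'
#' Eight states: `Start`, `N_B` (new block group), the four speed
#' adjustments `VX_plus`, `VX_minus`, `VY_plus`, `VY_minus`, the stop state
#' `V_zero`, and `Reset`. Eleven inputs: the four decoded classes (`left`,
#' `right`, `ton`, `foot`), the command-count comparisons (`P_eq`, `P_plus`,
#' `P_minus_moving` -- count decreased while still moving), the game events
#' (`Touch` wall contact, `Fallen` landing, `Cross` overflow) and `Null`
#' (no command decoded).
#'
#' @return Character vector of names.
#' @export
fsa_states <- function() {
  c("Start", "N_B", "VX_plus", "VX_minus", "VY_plus", "VY_minus",
    "V_zero", "Reset")
}

#' @rdname fsa_states
#' @export
fsa_inputs <- function() {
  c("left", "right", "ton", "foot", "P_eq", "P_plus", "P_minus_moving",
    "Touch", "Fallen", "Cross", "Null")
}

## transition table: rows = inputs, columns = states. NA = self-loop.
## "Start" and "V_zero" share a column in the source control table; both
## columns here carry the same entries.
fsa_table <- local({
  S <- fsa_states(); I <- fsa_inputs()
  tab <- matrix(NA_character_, length(I), length(S),
                dimnames = list(I, S))
  sv <- c("Start", "V_zero")                      # shared column
  vstates <- c("VX_plus", "VX_minus", "VY_plus", "VY_minus")
  ## direction commands
  tab["left", c(sv, "VX_minus", "VY_plus", "VY_minus")] <- "VX_plus"
  tab["right", c(sv, "VX_plus", "VY_plus", "VY_minus")] <- "VX_minus"
  tab["ton", c(sv, "VX_plus", "VX_minus", "VY_plus")] <- "VY_minus"
  tab["foot", c(sv, "VX_plus", "VX_minus", "VY_minus")] <- "VY_plus"
  ## count comparisons keep the current adjustment active
  for (i in c("P_eq", "P_plus", "P_minus_moving"))
    tab[i, vstates] <- vstates
  ## events
  tab["Touch", c(sv, vstates, "N_B")] <- "V_zero"
  tab["Fallen", vstates] <- "N_B"
  tab["Cross", c(sv, vstates, "N_B")] <- "Reset"
  tab["Cross", "Reset"] <- "Reset"
  tab["Null", "N_B"] <- "V_zero"
  tab
})

#' One step of the shared-control automaton
#'
#' Total function over the 8 x 11 (state, input) space; pairs absent from
#' the control table leave the state unchanged.
#'
#' @param state Current state (see [fsa_states()]).
#' @param input Input symbol (see [fsa_inputs()]).
#' @return Next state.
#' @export
#' @examples
#' fsa_step("Start", "left")     # "VX_plus"
#' fsa_step("VX_plus", "Touch")  # "V_zero"
fsa_step <- function(state, input) {
  if (!state %in% fsa_states()) mibci_stop("unknown state: ", state)
  if (!input %in% fsa_inputs()) mibci_stop("unknown input: ", input)
  nxt <- fsa_table[input, state]
  if (is.na(nxt)) state else nxt
}

#' Map a decoded imagery class to a lateral direction
#'
#' Foot moves the block group towards the foot plane (positive y), tongue
#' towards the tongue plane (negative y), left hand positive x, right hand
#' negative x. Idle carries no command.
#'
#' @param mi_class One of [mi_classes()] or `"idle"`.
#' @return Named numeric length-2 `c(dx, dy)` in \{-1, 0, 1\}, or `NULL`
#'   for idle.
#' @export
mi_to_direction <- function(mi_class) {
  switch(mi_class,
         foot = c(dx = 0, dy = 1),
         tongue = c(dx = 0, dy = -1),
         left_hand = c(dx = 1, dy = 0),
         right_hand = c(dx = -1, dy = 0),
         idle = NULL,
         mibci_stop("unknown class: ", mi_class))
}

## FSA input symbol corresponding to a decoded class
class_to_symbol <- function(mi_class) {
  switch(mi_class,
         foot = "foot", tongue = "ton",
         left_hand = "left", right_hand = "right",
         "Null")
}
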