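# The 14 condition->effect rules of the sequencing task. Conditions are
# weighted dot products on cortical buffers (the utilities the BG selects
# over); effects set a fixed pointer into a target buffer through the
# disinhibited thalamic channel.

rule <- function(name, condition, effects) {
  stopifnot(length(condition) >= 1, length(effects) >= 1)
  list(name = name, condition = condition, effects = effects)
}

term <- function(buffer, pointer, weight = 1) {
  list(buffer = buffer, pointer = pointer, weight = weight)
}

effect <- function(buffer, pointer, gain = 1) {
  list(buffer = buffer, pointer = pointer, gain = gain)
}

#' The action rules of the syllable sequencing task
#'
#' Fourteen rules in four classes: (1) start - the visual cue BA loads the
#' phonemic buffer with BA; (2) idle - a blank screen (visual ZERO) sets the
#' phonemic buffer to NEUTRAL; (3) speak(S), one per syllable - a phonemic
#' syllable S sets the premotor and auditory-expectation buffers to S and the
#' motor buffer to S_EXEC; (4) advance(S), one per syllable - somatosensory
#' feedback S_EXEC sets the phonemic buffer to the next syllable in the
#' cycle.
#'
#' The idle rule's condition is down-weighted (default 0.35): the screen
#' shows ZERO for nearly the whole trial, so at full weight this rule would
#' permanently compete with the sequencing rules; down-weighted it provides a
#' resting background utility that never outcompetes an active sequencing
#' rule.
#'
#' @param idle_weight Condition weight of the idle rule.
#' @param phonemic_gain Injection gain of effects targeting the (recurrent)
#'   phonemic buffer; above 1 so a newly selected syllable overtakes the
#'   decaying previous one quickly.
#' @param effect_gain Injection gain of all other effects.
#' @return List of 14 rules, in the fixed channel order start, idle,
#'   speak(BA..KA), advance(BA..KA).
#' @export
action_rules <- function(idle_weight = 0.35, phonemic_gain = 3.5,
                         effect_gain = 1.8) {
  rules <- list(
    rule("start", list(term("visual", "BA")),
         list(effect("phonemic", "BA", phonemic_gain))),
    rule("idle", list(term("visual", "ZERO", idle_weight)),
         list(effect("phonemic", "NEUTRAL", effect_gain)))
  )
  for (s in syllables()) {
    rules[[length(rules) + 1L]] <-
      rule(paste0("speak_", s), list(term("phonemic", s)),
           list(effect("premotor", s, effect_gain),
                effect("auditory", s, effect_gain),
                effect("motor", exec_pointer(s), effect_gain)))
  }
  for (s in syllables()) {
    rules[[length(rules) + 1L]] <-
      rule(paste0("advance_", s), list(term("somatosensory", exec_pointer(s))),
           list(effect("phonemic", next_syllable(s), phonemic_gain)))
  }
  rules
}
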