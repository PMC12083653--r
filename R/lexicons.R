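# Cue lexicons shared by the pattern annotator and the synthetic note templates.
# Order encodes rule precedence: rarer, more specific statuses first so that
# e.g. "previously married" phrasing cannot shadow a widow/divorce cue.

marital_cue_lexicon <- function() {
  list(
    WIDOWED   = "\\bwidowed\\b|\\bwidow\\b|\\bwidower\\b",
    DIVORCED  = "\\bdivorced\\b|\\bdivorce\\b",
    SEPARATED = "\\bseparated\\b",
    MARRIED   = "\\bmarried\\b|\\bhusband\\b|\\bwife\\b|\\bspouse\\b",
    PARTNERED = "\\bgirlfriend\\b|\\bboyfriend\\b|\\bpartner\\b|significant other",
    SINGLE    = "\\bsingle\\b|\\bunmarried\\b"
  )
}

# Living-arrangement cues. ALONE and WITH_OTHERS are checked before WITH_FAMILY
# so "lives in a group home with others" is not swallowed by the family rule.
living_cue_lexicon <- function() {
  list(
    ALONE       = "liv(es|ing) alone",
    WITH_OTHERS = "liv(es|ing) (with a roommate|with friends|in a group home)",
    WITH_FAMILY = paste0(
      "liv(es|ing) (at home )?with (his |her |their )?",
      "(wife|husband|spouse|partner|girlfriend|boyfriend|significant other|",
      "family|daughter|son|mother|father)"
    )
  )
}

cohab_partner_pattern <- function() {
  paste0(
    "liv(es|ing) (at home )?with (his |her |their )?",
    "(wife|husband|spouse|partner|girlfriend|boyfriend|significant other)"
  )
}

cohab_alone_pattern <- function() "liv(es|ing) alone"

first_cue_match <- function(text, lexicon, fallback) {
  text <- tolower(text)
  for (lab in names(lexicon)) {
    if (grepl(lexicon[[lab]], text, perl = TRUE)) return(lab)
  }
  fallback
}
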