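# Seed lexicon for risk-of-bias reporting detection.
#
# These patterns are a starting point, not a fixed vocabulary: they are
# matched against normalized (lowercased, whitespace-collapsed) text, use
# only the portable regular-expression core (character classes, alternation,
# bounded repetition; no backreferences), and are meant to be copied and
# edited for other literatures. Exclusion patterns suppress any inclusion
# match whose span they overlap.
randomization:
  include:
    - id: ri1
      pattern: "random(ly)? (assigned|allocated|divided|distributed)"
    - id: ri2
      pattern: "randomi[sz](ed|ation) ?(in)?to .{0,40}group"
    - id: ri3
      pattern: "random allocation"
    - id: ri4
      pattern: "randomi[sz]ation (schedule|sequence|list)"
    - id: ri5
      pattern: "random number (table|generator)"
  exclude:
    - id: rx1
      pattern: "random hexamer"
    - id: rx2
      pattern: "random primers?"
    - id: rx3
      pattern: "random(ly)? selected (field|section|area)s?"
    - id: rx4
      pattern: "random[- ]effects?"
    - id: rx5
      pattern: "randomly distributed (across|over|throughout)"
blinding:
  include:
    - id: bi1
      pattern: "blind(ed)? (fashion|manner|assessment|evaluation|observer|investigator|examiner)"
    - id: bi2
      pattern: "in a blinded"
    - id: bi3
      pattern: "(observer|assessor|investigator)[- ]blind(ed)?"
    - id: bi4
      pattern: "masked to (the )?(group|treatment)"
    - id: bi5
      pattern: "unaware of (the )?(group|treatment) (allocation|assignment)"
  exclude:
    - id: bx1
      pattern: "blind[- ]end(ed)?"
    - id: bx2
      pattern: "double[- ]blind (placebo|clinical|trial)"
    - id: bx3
      pattern: "blindness"
    - id: bx4
      pattern: "blinded clinical (trial|study)"
samplesize:
  include:
    - id: si1
      pattern: "sample size (calculation|estimation|was (calculated|determined|estimated))"
    - id: si2
      pattern: "power (calculation|analysis)"
    - id: si3
      pattern: "a priori power"
    - id: si4
      pattern: "statistical power of .{0,20}(0\\.[89]\\d*|[89]\\d%)"
    - id: si5
      pattern: "to detect a (difference|effect) .{0,60}power"
  exclude:
    - id: sx1
      pattern: "high[- ]power(ed)? fields?"
    - id: sx2
      pattern: "power supply"
    - id: sx3
      pattern: "spectral power"
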