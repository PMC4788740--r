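# Synthetic demonstration filter for e-cigarette-style content.
# This is NOT the authoritative keyword list of any published study; it
# emulates the structure such filters share: keyword categories for
# devices, brands and behavior, a co-occurrence exclusion rule, and a
# promoting-account handle rule.
keywords:
  - {term: e-cig, category: device, mode: word}
  - {term: ecig, category: device, mode: word}
  - {term: e-cigarette, category: device, mode: word}
  - {term: atomizer, category: device, mode: word}
  - {term: cartomizer, category: device, mode: word}
  - {term: vape pen, category: device, mode: phrase}
  - {term: blucig, category: brand, mode: word}
  - {term: "#vapelife", category: behavior, mode: hashtag}
  - {term: vape, category: behavior, mode: word}
  - {term: vaping, category: behavior, mode: word}
  - {term: perfume, category: exclusion-helper, mode: word}
  - {term: "@blucigs", category: brand, mode: handle}
rule: >
  e-cig OR ecig OR e-cigarette OR atomizer OR cartomizer OR "vape pen"
  OR blucig OR "#vapelife" OR vape OR vaping
exclusions:
  - [atomizer, perfume]
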