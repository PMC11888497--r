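language: nl
header: >
  U bent een ervaren klinisch geneticus. Hieronder staat de beschrijving van
  een patiënt. De aandoening wordt veroorzaakt door een genetische ziekte.
  Geef een geordende differentiaaldiagnose als genummerde lijst van
  kandidaat-diagnoses, de meest waarschijnlijke eerst, bijvoorbeeld:
example_output: |
  1. Most likely candidate disease
  2. Second candidate disease
  3. Third candidate disease
answer_directive: "Geef de differentiaaldiagnose in het Engels (in English)."
sex_age: "De patiënt was {sex} van {age} oud."
sex_age_no_age: "De patiënt was {sex}."
sex_male: "een man"
sex_female: "een vrouw"
sex_other: "een persoon van een ander geslacht"
sex_unknown: "een persoon"
age_years: "{n} jaar"
age_months: "{n} maanden"
age_days: "{n} dagen"
disease_onset: "De ziekte openbaarde zich op de leeftijd van {age}."
feature_onset: "{label} (begin op de leeftijd van {age})"
observed: "De patiënt vertoonde de volgende verschijnselen en symptomen: {labels}."
excluded: "De volgende verschijnselen en symptomen werden uitgesloten: {labels}."
list_sep: ", "
list_final: " en "
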