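language: cs
header: >
  Jste zkušený klinický genetik. Níže je uveden popis pacienta. Onemocnění
  je způsobeno genetickou chorobou. Uveďte seřazenou diferenciální diagnózu
  jako číslovaný seznam kandidátních diagnóz, nejpravděpodobnější jako
  první, například:
example_output: |
  1. Most likely candidate disease
  2. Second candidate disease
  3. Third candidate disease
answer_directive: "Uveďte diferenciální diagnózu v angličtině (in English)."
sex_age: "Pacientem byl {sex} ve věku {age}."
sex_age_no_age: "Pacientem byl {sex}."
sex_male: "muž"
sex_female: "žena"
sex_other: "osoba jiného pohlaví"
sex_unknown: "osoba"
age_years: "{n} let"
age_months: "{n} měsíců"
age_days: "{n} dnů"
disease_onset: "Onemocnění se projevilo ve věku {age}."
feature_onset: "{label} (začátek ve věku {age})"
observed: "Pacient vykazoval následující příznaky a projevy: {labels}."
excluded: "Následující příznaky a projevy byly vyloučeny: {labels}."
list_sep: ", "
list_final: " a "
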