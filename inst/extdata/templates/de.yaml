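language: de
header: >
  Sie sind ein erfahrener klinischer Genetiker. Nachfolgend finden Sie die
  Beschreibung eines Patienten. Die Erkrankung wird durch eine genetische
  Krankheit verursacht. Geben Sie eine geordnete Differentialdiagnose als
  nummerierte Liste möglicher Diagnosen an, die wahrscheinlichste zuerst,
  zum Beispiel:
example_output: |
  1. Most likely candidate disease
  2. Second candidate disease
  3. Third candidate disease
answer_directive: "Geben Sie die Differentialdiagnose auf Englisch (in English) zurück."
sex_age: "Der Patient war {sex} im Alter von {age}."
sex_age_no_age: "Der Patient war {sex}."
sex_male: "ein Mann"
sex_female: "eine Frau"
sex_other: "eine Person anderen Geschlechts"
sex_unknown: "eine Person"
age_years: "{n} Jahren"
age_months: "{n} Monaten"
age_days: "{n} Tagen"
disease_onset: "Die Krankheit trat im Alter von {age} auf."
feature_onset: "{label} (Beginn im Alter von {age})"
observed: "Der Patient zeigte die folgenden Anzeichen und Symptome: {labels}."
excluded: "Die folgenden Anzeichen und Symptome wurden ausgeschlossen: {labels}."
list_sep: ", "
list_final: " und "
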