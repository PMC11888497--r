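language: it
header: >
  Lei è un esperto genetista clinico. Di seguito è riportata la descrizione
  di un paziente. La condizione è causata da una malattia genetica. Fornisca
  una diagnosi differenziale ordinata come elenco numerato di diagnosi
  candidate, la più probabile per prima, ad esempio:
example_output: |
  1. Most likely candidate disease
  2. Second candidate disease
  3. Third candidate disease
answer_directive: "Restituisca la diagnosi differenziale in inglese (in English)."
sex_age: "Il paziente era {sex} di {age}."
sex_age_no_age: "Il paziente era {sex}."
sex_male: "un maschio"
sex_female: "una femmina"
sex_other: "una persona di altro sesso"
sex_unknown: "una persona"
age_years: "{n} anni"
age_months: "{n} mesi"
age_days: "{n} giorni"
disease_onset: "La malattia si è manifestata all'età di {age}."
feature_onset: "{label} (esordio all'età di {age})"
observed: "Il paziente presentava i seguenti segni e sintomi: {labels}."
excluded: "Sono stati esclusi i seguenti segni e sintomi: {labels}."
list_sep: ", "
list_final: " e "
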