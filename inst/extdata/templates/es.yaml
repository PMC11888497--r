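language: es
header: >
  Usted es un genetista clínico experto. A continuación se describe un
  paciente. La afección está causada por una enfermedad genética.
  Proporcione un diagnóstico diferencial ordenado como una lista numerada de
  diagnósticos candidatos, el más probable primero, por ejemplo:
example_output: |
  1. Most likely candidate disease
  2. Second candidate disease
  3. Third candidate disease
answer_directive: "Devuelva el diagnóstico diferencial en inglés (in English)."
sex_age: "El paciente era {sex} de {age} de edad."
sex_age_no_age: "El paciente era {sex}."
sex_male: "un varón"
sex_female: "una mujer"
sex_other: "una persona de otro sexo"
sex_unknown: "una persona"
age_years: "{n} años"
age_months: "{n} meses"
age_days: "{n} días"
disease_onset: "La enfermedad se manifestó a la edad de {age}."
feature_onset: "{label} (inicio a la edad de {age})"
observed: "El paciente presentaba los siguientes signos y síntomas: {labels}."
excluded: "Se excluyeron los siguientes signos y síntomas: {labels}."
list_sep: ", "
list_final: " y "
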