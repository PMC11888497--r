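language: en
header: >
  You are an expert clinical geneticist. Below is the description of a
  patient. The condition is caused by a genetic disease. Provide a ranked
  differential diagnosis as a numbered list of candidate diagnoses, the most
  likely first, for example:
example_output: |
  1. Most likely candidate disease
  2. Second candidate disease
  3. Third candidate disease
answer_directive: "Return the differential diagnosis in English."
sex_age: "The patient was a {sex} aged {age}."
sex_age_no_age: "The patient was a {sex}."
sex_male: "male"
sex_female: "female"
sex_other: "person of other sex"
sex_unknown: "individual"
age_years: "{n} years"
age_months: "{n} months"
age_days: "{n} days"
disease_onset: "The disease manifested at the age of {age}."
feature_onset: "{label} (onset at {age})"
observed: "The patient presented with the following signs and symptoms: {labels}."
excluded: "The following signs and symptoms were explicitly excluded: {labels}."
list_sep: ", "
list_final: " and "
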