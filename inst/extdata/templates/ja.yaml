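language: ja
header: >
  あなたは経験豊富な臨床遺伝専門医です。以下は患者の記述です。この病態は遺伝性疾患に
  よるものです。候補診断を可能性の高い順に番号付きリストで示し、順位付けした鑑別診断を
  提示してください。例：
example_output: |
  1. Most likely candidate disease
  2. Second candidate disease
  3. Third candidate disease
answer_directive: "鑑別診断は英語（in English）で回答してください。"
sex_age: "患者は{age}の{sex}であった。"
sex_age_no_age: "患者は{sex}であった。"
sex_male: "男性"
sex_female: "女性"
sex_other: "その他の性別の人"
sex_unknown: "人"
age_years: "{n}歳"
age_months: "生後{n}か月"
age_days: "生後{n}日"
disease_onset: "疾患は{age}で発症した。"
feature_onset: "{label}（{age}で発症）"
observed: "患者には以下の徴候および症状が認められた：{labels}。"
excluded: "以下の徴候および症状は除外された：{labels}。"
list_sep: "、"
list_final: "および"
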