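language: zh
header: >
  您是一位资深临床遗传学专家。以下是一名患者的描述。该病情由遗传性疾病引起。
  请给出按可能性排序的鉴别诊断，以编号列表形式列出候选诊断，最可能的排在首位，例如：
example_output: |
  1. Most likely candidate disease
  2. Second candidate disease
  3. Third candidate disease
answer_directive: "请用英文（in English）返回鉴别诊断。"
sex_age: "患者为一名{age}的{sex}。"
sex_age_no_age: "患者为一名{sex}。"
sex_male: "男性"
sex_female: "女性"
sex_other: "其他性别者"
sex_unknown: "个体"
age_years: "{n}岁"
age_months: "{n}个月大"
age_days: "{n}天大"
disease_onset: "疾病于患者{age}时起病。"
feature_onset: "{label}（{age}时出现）"
observed: "患者表现出以下体征和症状：{labels}。"
excluded: "已排除以下体征和症状：{labels}。"
list_sep: "、"
list_final: "和"
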