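language: tr
header: >
  Deneyimli bir klinik genetik uzmanısınız. Aşağıda bir hastanın tanımı yer
  almaktadır. Durum genetik bir hastalıktan kaynaklanmaktadır. Aday tanıları
  en olasıdan başlayarak numaralandırılmış bir liste halinde sıralı ayırıcı
  tanı olarak veriniz, örneğin:
example_output: |
  1. Most likely candidate disease
  2. Second candidate disease
  3. Third candidate disease
answer_directive: "Ayırıcı tanıyı İngilizce (in English) olarak veriniz."
sex_age: "Hasta {age} bir {sex} idi."
sex_age_no_age: "Hasta bir {sex} idi."
sex_male: "erkek"
sex_female: "kadın"
sex_other: "diğer cinsiyetten kişi"
sex_unknown: "kişi"
age_years: "{n} yaşında"
age_months: "{n} aylık"
age_days: "{n} günlük"
disease_onset: "Hastalık hasta {age} iken başladı."
feature_onset: "{label} ({age} iken başlangıç)"
observed: "Hastada şu bulgu ve belirtiler mevcuttu: {labels}."
excluded: "Şu bulgu ve belirtiler dışlandı: {labels}."
list_sep: ", "
list_final: " ve "
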