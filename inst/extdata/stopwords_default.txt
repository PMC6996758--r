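の
は
が
を
に
で
と
も
へ
や
から
まで
です
ます
する
いる
ある
なる
れる
られる
こと
もの
これ
それ
あれ
ね
よ
な
か
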