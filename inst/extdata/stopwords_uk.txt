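# Reconstructed Ukrainian stopword list: closed-class lemmas (pronouns,
# prepositions, conjunctions, particles, auxiliaries) plus a few
# high-frequency discourse items. This is a reconstruction assembled from
# closed-class universal-POS categories, not the original curated list used
# to build any particular released corpus.
і
й
та
але
а
або
чи
що
щоб
як
якщо
коли
бо
тому
тож
же
ж
б
би
не
ні
так
це
цей
ця
це
ці
той
та
те
ті
весь
вся
все
всі
я
ти
він
вона
воно
ми
ви
вони
мій
твій
свій
наш
ваш
їхній
себе
хто
хтось
ніхто
ніщо
щось
який
якийсь
кожен
інший
сам
у
в
на
з
із
зі
до
від
по
про
за
під
над
при
без
через
між
для
після
перед
серед
біля
крім
завдяки
щодо
бути
є
був
була
було
були
мати
могти
вже
ще
тільки
лише
навіть
також
теж
дуже
тут
там
тоді
зараз
потім
де
куди
звідки
чому
навіщо
отже
однак
проте
хоча
аби
нехай
хай
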