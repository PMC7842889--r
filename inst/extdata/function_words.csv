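word,class
a,article
an,article
the,article
about,preposition
above,preposition
across,preposition
after,preposition
against,preposition
along,preposition
among,preposition
around,preposition
at,preposition
before,preposition
behind,preposition
below,preposition
beneath,preposition
beside,preposition
between,preposition
beyond,preposition
by,preposition
despite,preposition
down,preposition
during,preposition
except,preposition
for,preposition
from,preposition
in,preposition
inside,preposition
into,preposition
near,preposition
of,preposition
off,preposition
on,preposition
onto,preposition
out,preposition
outside,preposition
over,preposition
past,preposition
since,preposition
through,preposition
throughout,preposition
to,preposition
toward,preposition
towards,preposition
under,preposition
until,preposition
up,preposition
upon,preposition
with,preposition
within,preposition
without,preposition
am,auxiliary
is,auxiliary
are,auxiliary
was,auxiliary
were,auxiliary
be,auxiliary
been,auxiliary
being,auxiliary
have,auxiliary
has,auxiliary
had,auxiliary
having,auxiliary
do,auxiliary
does,auxiliary
did,auxiliary
will,auxiliary
shall,auxiliary
would,auxiliary
should,auxiliary
can,auxiliary
could,auxiliary
may,auxiliary
might,auxiliary
must,auxiliary
ought,auxiliary
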